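# Synthetic-data generator: birth-death species trees, Jukes-Cantor coding
# sequences, and intron complements shaped by explicit gain / loss /
# lateral-transfer / transposition events, with a complete ground-truth
# event log. Everything is driven by one integer seed.

#' Simulation configuration
#'
#' Bundles every tunable of the generator. Event rates are expected event
#' counts per tree branch (Poisson). Substitution rates are expected
#' substitutions per site per unit branch length under Jukes-Cantor.
#' Intron insertion sites are restricted to coding positions whose base is
#' T (the group I splice consensus: exonic T immediately 5' of the intron,
#' intron ending in G); those T sites and each intron's terminal G are held
#' fixed while sequences diverge.
#'
#' @param seed integer RNG seed.
#' @param n_taxa number of surviving leaves.
#' @param birth_rate,death_rate per-lineage birth-death rates.
#' @param subst_rate coding-sequence substitution rate.
#' @param intron_subst_rate intron substitution rate (group I intron cores
#'   are structurally constrained, so the default is of the same order as
#'   the coding rate).
#' @param cds_length_codons amino-acid codons in the coding sequence; the
#'   cdna additionally carries a stop codon, so its length is
#'   `3 * (cds_length_codons + 1)`. Default 393, a typical cytochrome b
#'   protein span.
#' @param intron_length_range min/max intron length in nt (default
#'   900-1800, the size range of the large fungal cob introns).
#' @param gain_rate,loss_rate,transfer_rate,transposition_rate per-branch
#'   event rates.
#' @param n_ancestral_families intron families seeded at the root.
#' @param site_pool optional integer vector of insertion points to draw
#'   from; by default all T positions of the root coding sequence away from
#'   the start and stop codons.
#' @param min_exon_nt minimum spacing between occupied insertion sites in
#'   one lineage, i.e. the shortest internal exon the generator will
#'   create (real cob exons go down to about 11 nt).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_taxa = 12L,
                              birth_rate = 1, death_rate = 0.3,
                              subst_rate = 0.05, intron_subst_rate = 0.05,
                              cds_length_codons = 393L,
                              intron_length_range = c(900L, 1800L),
                              gain_rate = 0.15, loss_rate = 0.3,
                              transfer_rate = 0.1,
                              transposition_rate = 0.05,
                              n_ancestral_families = 4L,
                              site_pool = NULL, min_exon_nt = 12L) {
  rates <- c(birth_rate = birth_rate, death_rate = death_rate,
             subst_rate = subst_rate, intron_subst_rate = intron_subst_rate,
             gain_rate = gain_rate, loss_rate = loss_rate,
             transfer_rate = transfer_rate,
             transposition_rate = transposition_rate)
  if (any(rates < 0)) cob_error("rates must be >= 0", "cobintron_bad_config")
  if (n_taxa < 1L) cob_error("n_taxa must be >= 1", "cobintron_bad_config")
  if (cds_length_codons < 10L)
    cob_error("cds_length_codons must be >= 10", "cobintron_bad_config")
  if (length(intron_length_range) != 2L ||
      intron_length_range[1] > intron_length_range[2] ||
      intron_length_range[1] < 2L)
    cob_error("invalid intron_length_range", "cobintron_bad_config")
  structure(c(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa)),
              as.list(rates),
              list(cds_length_codons = as.integer(cds_length_codons),
                   intron_length_range = as.integer(intron_length_range),
                   n_ancestral_families = as.integer(n_ancestral_families),
                   site_pool = site_pool,
                   min_exon_nt = as.integer(min_exon_nt))),
            class = "simulation_config")
}

## ---- species tree ----------------------------------------------------

#' Simulate a birth-death species tree
#'
#' Forward simulation of a linear birth-death process started from one
#' lineage and stopped the first time `n_taxa` lineages are alive; the
#' present is set just before the next event would fire, so the tree is
#' ultrametric with strictly positive branch lengths. The stem below the
#' first split is dropped, so under pure birth the expected root-to-tip
#' depth is `(H(n) - 1) / birth_rate` (harmonic number H).
#' Runs that go extinct are retried (at most 100 times).
#'
#' Uses the RNG; seed via `set.seed()` (done by [simulate_catalogue()]).
#'
#' @param config a [simulation_config()].
#' @return rooted ultrametric `phylo` with tips `t01`, `t02`, ...
#' @export
simulate_species_tree <- function(config) {
  b <- config$birth_rate; d <- config$death_rate
  n <- config$n_taxa
  for (try in seq_len(100L)) {
    lin <- sim_bd_once(n, b, d)
    if (!is.null(lin)) return(lineages_to_phylo(lin$tab, lin$present))
  }
  cob_error(sprintf(
    "birth-death simulation failed to reach %d surviving lineages in 100 tries (birth %g, death %g)",
    n, b, d), "cobintron_tree_nonconvergence")
}

sim_bd_once <- function(n, b, d) {
  # lineage table: parent, t_start, t_end (NA while alive), split flag
  parent <- c(0L); t_start <- c(0); t_end <- c(NA_real_); split <- c(FALSE)
  alive <- 1L
  t <- 0
  repeat {
    k <- length(alive)
    w <- rexp(1L, k * (b + d + 1e-300))
    if (k == n) return(list(tab = data.frame(parent, t_start, t_end, split),
                            present = t + w))
    t <- t + w
    i <- alive[sample.int(k, 1L)]
    if (runif(1L) < b / (b + d)) {
      # birth: lineage i splits into two daughters
      t_end[i] <- t; split[i] <- TRUE
      parent <- c(parent, i, i); t_start <- c(t_start, t, t)
      t_end <- c(t_end, NA_real_, NA_real_); split <- c(split, FALSE, FALSE)
      alive <- c(setdiff(alive, i), length(parent) - 1L, length(parent))
    } else {
      t_end[i] <- t
      alive <- setdiff(alive, i)
      if (!length(alive)) return(NULL)
    }
  }
}

lineages_to_phylo <- function(tab, present) {
  tab$t_end[is.na(tab$t_end)] <- present
  is_tip <- !tab$split & tab$t_end == present
  tip_ids <- which(is_tip)
  labels <- setNames(sprintf("t%02d", seq_along(tip_ids)), tip_ids)
  kids <- split(seq_len(nrow(tab)), tab$parent)
  build <- function(i) {
    len <- tab$t_end[i] - tab$t_start[i]
    if (tab$split[i]) {
      sub <- Filter(Negate(is.null), lapply(kids[[as.character(i)]], build))
      if (!length(sub)) return(NULL)
      if (length(sub) == 1L)                     # extinct side: splice out
        return(list(str = sub[[1]]$str, len = sub[[1]]$len + len))
      return(list(str = sprintf("(%s,%s)",
                                sprintf("%s:%.10f", sub[[1]]$str, sub[[1]]$len),
                                sprintf("%s:%.10f", sub[[2]]$str, sub[[2]]$len)),
                  len = len))
    }
    if (!is_tip[i]) return(NULL)
    list(str = labels[[as.character(i)]], len = len)
  }
  root <- build(1L)
  if (sum(is_tip) == 1L)
    return(ape::read.tree(text = sprintf("(%s:%.10f);", root$str, root$len)))
  ape::read.tree(text = paste0(root$str, ";"))
}

## ---- sequence evolution ----------------------------------------------

# genetic code table 4 (mold mitochondrial): TGA is Trp, stops are TAA/TAG
MITO_STOPS <- c("TAA", "TAG")

random_root_cds <- function(n_codons) {
  codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                            DNA_BASES, paste0))
  codons <- setdiff(codons, MITO_STOPS)
  body <- sample(codons, n_codons - 1L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Evolve one sequence under Jukes-Cantor
#'
#' Applies the exact JC69 transition over time `t`: each site changes with
#' probability `3/4 (1 - exp(-4 r t / 3))`, to one of the other three bases
#' uniformly. Sites in `frozen` never change.
#'
#' @param seq nucleotide string.
#' @param rate substitutions/site/unit time.
#' @param t elapsed time.
#' @param frozen integer positions held fixed.
#' @return evolved sequence string.
#' @export
jc_evolve <- function(seq, rate, t, frozen = integer(0)) {
  if (rate * t <= 0) return(seq)
  n <- nchar(seq)
  p <- 0.75 * (1 - exp(-4 * rate * t / 3))
  hits <- which(runif(n) < p)
  if (length(frozen)) hits <- setdiff(hits, frozen)
  if (!length(hits)) return(seq)
  chars <- seq_chars(seq)
  chars[hits] <- vapply(chars[hits], function(b) {
    alt <- DNA_BASES[DNA_BASES != b]
    if (length(alt) < 3L) alt <- DNA_BASES      # ambiguity codes: free draw
    alt[sample.int(length(alt), 1L)]
  }, character(1))
  paste(chars, collapse = "")
}

#' Evolve coding sequences along a tree
#'
#' The root coding sequence (uniform random codons, ATG start, TAA stop, no
#' internal stops under translation table 4) diverges along each branch
#' under Jukes-Cantor. Start and stop codons and the splice-consensus T
#' sites in `frozen` are preserved; substitutions creating an internal stop
#' codon are resampled.
#'
#' @param tree `phylo` with branch lengths.
#' @param config a [simulation_config()].
#' @param root_cds optional root coding sequence; generated if `NULL`.
#' @param frozen extra integer positions held fixed on every branch.
#' @return named character vector of leaf cdna sequences (plus the root
#'   sequence as attribute `"root_cds"`).
#' @export
evolve_coding_sequences <- function(tree, config, root_cds = NULL,
                                    frozen = integer(0)) {
  if (is.null(root_cds))
    root_cds <- random_root_cds(config$cds_length_codons + 1L)
  L <- nchar(root_cds)
  fixed <- unique(c(1:3, (L - 2):L, frozen))
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- root_cds
  ord <- reorder_edges_preorder(tree)
  for (k in ord) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    s <- jc_evolve(seqs[[u]], config$subst_rate, tree$edge.length[k], fixed)
    seqs[[v]] <- fix_internal_stops(s, seqs[[u]])
  }
  out <- setNames(unlist(seqs[seq_len(ntip)]), tree$tip.label)
  attr(out, "root_cds") <- root_cds
  out
}

# preorder (root -> tips) ordering of edge indices
reorder_edges_preorder <- function(tree) {
  e <- tree$edge
  root <- length(tree$tip.label) + 1L
  ord <- integer(0)
  stack <- which(e[, 1] == root)
  while (length(stack)) {
    k <- stack[1]; stack <- stack[-1]
    ord <- c(ord, k)
    stack <- c(which(e[, 1] == e[k, 2]), stack)
  }
  ord
}

# revert any codon that mutated into TAA/TAG back to its parent codon
fix_internal_stops <- function(seq, parent_seq) {
  n_codon <- nchar(seq) %/% 3L
  starts <- 3L * (seq_len(n_codon - 1L) - 1L) + 1L   # skip terminal stop
  codons <- substring(seq, starts, starts + 2L)
  bad <- which(codons %in% MITO_STOPS)
  if (!length(bad)) return(seq)
  chars <- seq_chars(seq); pchars <- seq_chars(parent_seq)
  for (i in bad) {
    idx <- (3L * (i - 1L) + 1L):(3L * i)
    chars[idx] <- pchars[idx]
  }
  paste(chars, collapse = "")
}

## ---- intron history ---------------------------------------------------

random_intron_seq <- function(len) {
  paste0(substr(random_dna(len), 1L, len - 1L), "G")
}

# sites at least `gap` nt away from every occupied site
free_sites <- function(pool, occupied, gap) {
  if (!length(occupied)) return(pool)
  pool[vapply(pool, function(p) all(abs(p - occupied) >= gap), logical(1))]
}

default_site_pool <- function(root_cds) {
  L <- nchar(root_cds)
  p <- which(seq_chars(root_cds) == "T")
  p[p >= 6L & p <= L - 6L]
}

#' Simulate the intron gain/loss/transfer/transposition history
#'
#' Ancestral intron families are seeded at the root at distinct insertion
#' sites; their sequences diverge along branches under Jukes-Cantor (with
#' the terminal G fixed). Per-branch event counts are Poisson with the
#' configured rates and event times are uniform within the branch:
#' \describe{
#'   \item{loss}{removes one present family from the lineage, precisely.}
#'   \item{gain}{inserts a novel family (fresh id, fresh sequence) at a free
#'     site.}
#'   \item{transfer}{copies a contemporaneous lineage's family sequence
#'     verbatim (it then continues to diverge), at the donor's site; this
#'     yields near-identical introns in possibly distant leaves.}
#'   \item{transposition}{relocates one family to a new free site (at most
#'     once per family per branch).}
#' }
#' Site collisions are avoided by sampling only free sites; events with no
#' eligible target are dropped silently (and not logged).
#'
#' @param tree ultrametric `phylo`.
#' @param config a [simulation_config()].
#' @param site_pool integer insertion points available to families.
#' @return list with `complements` (data frame: species_id, family_id,
#'   insertion_point, sequence), `events` (the true event log) and
#'   `families` (data frame of family metadata).
#' @export
simulate_intron_history <- function(tree, config, site_pool) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  depth <- ape::node.depth.edgelength(tree)
  edges <- tree$edge
  rate <- config$intron_subst_rate

  node_label <- function(v) if (v <= ntip) tree$tip.label[v]
                            else sprintf("n%d", v)

  # ancestral families, at mutually spaced sites
  gap <- config$min_exon_nt
  fam_pos <- integer(0)
  for (i in seq_len(config$n_ancestral_families)) {
    free <- free_sites(site_pool, fam_pos, gap)
    if (!length(free)) break
    fam_pos <- c(fam_pos, free[sample.int(length(free), 1L)])
  }
  fam_pos <- sort(fam_pos)
  nf <- length(fam_pos)
  next_fid <- nf + 1L
  fam_meta <- data.frame(
    family_id = seq_len(nf),
    origin = rep("ancestral", nf),
    birth_position = fam_pos,
    length = vapply(seq_len(nf), function(i)
      sample.int(config$intron_length_range[2] -
                   config$intron_length_range[1] + 1L, 1L) +
        config$intron_length_range[1] - 1L, integer(1)))
  root_state <- lapply(seq_len(nf), function(i)
    list(fid = i, pos = fam_pos[i],
         seq = random_intron_seq(fam_meta$length[i]), t_seq = 0))
  names(root_state) <- as.character(seq_len(nf))

  # schedule: per-edge events plus node/leaf finalizations
  sched <- list()
  kinds <- c(gain = config$gain_rate, loss = config$loss_rate,
             transfer = config$transfer_rate,
             transposition = config$transposition_rate)
  for (k in seq_len(nrow(edges))) {
    t0 <- depth[edges[k, 1]]; t1 <- depth[edges[k, 2]]
    for (kind in names(kinds)) {
      cnt <- rpois(1L, kinds[[kind]])
      if (cnt > 0L)
        sched[[length(sched) + 1L]] <-
          data.frame(time = runif(cnt, t0, t1), kind = kind, edge = k)
    }
  }
  for (v in seq_len(ntip + tree$Nnode))
    if (v != root)
      sched[[length(sched) + 1L]] <-
        data.frame(time = depth[v], kind = if (v <= ntip) "leaf" else "node",
                   edge = which(edges[, 2] == v))
  sched <- do.call(rbind, sched)
  # node/leaf finalizations sort after same-time branch events
  sched <- sched[order(sched$time, sched$kind %in% c("leaf", "node")), ,
                 drop = FALSE]

  node_states <- vector("list", ntip + tree$Nnode)
  node_states[[root]] <- root_state
  edge_states <- vector("list", nrow(edges))
  transposed_on_edge <- vector("list", nrow(edges))
  events <- list()
  complements <- list()

  get_edge_state <- function(k) {
    if (is.null(edge_states[[k]]))
      edge_states[[k]] <<- node_states[[edges[k, 1]]]
    edge_states[[k]]
  }
  evolve_to <- function(st, t) {
    for (nm in names(st)) {
      f <- st[[nm]]
      if (t > f$t_seq) {
        last <- nchar(f$seq)
        f$seq <- jc_evolve(f$seq, rate, t - f$t_seq, frozen = last)
        f$t_seq <- t
        st[[nm]] <- f
      }
    }
    st
  }
  log_event <- function(kind, k, t, fid, pos, donor_edge = NA_integer_) {
    cp <- codon_and_phase(pos)
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, branch = node_label(edges[k, 2]),
      branch_child = edges[k, 2], time = t, family_id = fid,
      insertion_point = pos, codon = cp$codon, phase = cp$phase,
      donor_branch = if (is.na(donor_edge)) NA_character_
                     else node_label(edges[donor_edge, 2]),
      donor_child = if (is.na(donor_edge)) NA_integer_
                    else edges[donor_edge, 2])
  }

  for (r in seq_len(nrow(sched))) {
    t <- sched$time[r]; kind <- sched$kind[r]; k <- sched$edge[r]
    st <- evolve_to(get_edge_state(k), t)
    if (kind == "node" || kind == "leaf") {
      v <- edges[k, 2]
      if (kind == "node") node_states[[v]] <- st
      else {
        sp <- tree$tip.label[v]
        if (length(st))
          complements[[sp]] <- data.frame(
            species_id = sp,
            family_id = vapply(st, `[[`, integer(1), "fid"),
            insertion_point = vapply(st, `[[`, numeric(1), "pos"),
            sequence = vapply(st, `[[`, character(1), "seq"))
      }
    } else if (kind == "gain") {
      free <- free_sites(site_pool, vapply(st, `[[`, numeric(1), "pos"), gap)
      if (length(free)) {
        pos <- free[sample.int(length(free), 1L)]
        len <- sample.int(config$intron_length_range[2] -
                            config$intron_length_range[1] + 1L, 1L) +
          config$intron_length_range[1] - 1L
        fid <- next_fid; next_fid <- next_fid + 1L
        st[[as.character(fid)]] <- list(fid = fid, pos = pos,
                                        seq = random_intron_seq(len),
                                        t_seq = t)
        fam_meta <- rbind(fam_meta, data.frame(
          family_id = fid, origin = "gain", birth_position = pos,
          length = len))
        log_event("gain", k, t, fid, pos)
      }
    } else if (kind == "loss") {
      if (length(st)) {
        i <- sample.int(length(st), 1L)
        log_event("loss", k, t, st[[i]]$fid, st[[i]]$pos)
        st[[i]] <- NULL
      }
    } else if (kind == "transfer") {
      active <- which(depth[edges[, 1]] < t & t <= depth[edges[, 2]])
      active <- setdiff(active, k)
      have <- vapply(st, `[[`, integer(1), "fid")
      occ <- vapply(st, `[[`, numeric(1), "pos")
      cand <- list()
      for (j in active) {
        dst <- get_edge_state(j)
        for (f in dst)
          if (!(f$fid %in% have) && all(abs(f$pos - occ) >= gap))
            cand[[length(cand) + 1L]] <- c(j, f$fid)
      }
      if (length(cand)) {
        pick <- cand[[sample.int(length(cand), 1L)]]
        j <- pick[1]; fid <- pick[2]
        edge_states[[j]] <- evolve_to(get_edge_state(j), t)
        donor <- edge_states[[j]][[as.character(fid)]]
        st[[as.character(fid)]] <- list(fid = fid, pos = donor$pos,
                                        seq = donor$seq, t_seq = t)
        log_event("transfer", k, t, fid, donor$pos, donor_edge = j)
      }
    } else if (kind == "transposition") {
      done <- transposed_on_edge[[k]] %||% integer(0)
      movable <- which(!vapply(st, `[[`, integer(1), "fid") %in% done)
      free <- free_sites(site_pool, vapply(st, `[[`, numeric(1), "pos"), gap)
      if (length(movable) && length(free)) {
        i <- movable[sample.int(length(movable), 1L)]
        pos <- free[sample.int(length(free), 1L)]
        st[[i]]$pos <- pos
        transposed_on_edge[[k]] <- c(done, st[[i]]$fid)
        log_event("transposition", k, t, st[[i]]$fid, pos)
      }
    }
    edge_states[[k]] <- st
  }

  comp <- if (length(complements)) do.call(rbind, complements)
          else data.frame(species_id = character(0),
                          family_id = integer(0),
                          insertion_point = numeric(0),
                          sequence = character(0))
  rownames(comp) <- NULL
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(kind = character(0), branch = character(0),
                        branch_child = integer(0), time = numeric(0),
                        family_id = integer(0), insertion_point = numeric(0),
                        codon = integer(0), phase = integer(0),
                        donor_branch = character(0),
                        donor_child = integer(0))
  list(complements = comp, events = ev, families = fam_meta)
}

## ---- rendering --------------------------------------------------------

#' Render genomic sequences from coding sequences and intron complements
#'
#' Splices each intron into its host cdna at its insertion point. Every
#' intron must end in G and sit after a T coding base (the screened site
#' pool guarantees this for simulated complements); violations raise an
#' error. The resulting gdna length equals the cdna length plus the summed
#' intron lengths.
#'
#' @param cdnas named character vector of coding sequences.
#' @param complements data frame with `species_id`, `insertion_point`,
#'   `sequence` (one row per intron; species without rows are intronless).
#' @param divisions optional named character vector of taxon divisions.
#' @return list of [gene_record()] objects.
#' @export
render_genomic_sequences <- function(cdnas, complements, divisions = NULL) {
  lapply(sort(names(cdnas)), function(sp) {
    cdna <- cdnas[[sp]]
    rows <- complements[complements$species_id == sp, , drop = FALSE]
    rows <- rows[order(rows$insertion_point), , drop = FALSE]
    gdna <- cdna
    if (nrow(rows)) {
      if (anyDuplicated(rows$insertion_point))
        cob_error(sprintf("%s: two introns at one insertion point", sp),
                  "cobintron_site_collision")
      for (i in rev(seq_len(nrow(rows)))) {
        p <- rows$insertion_point[i]; s <- rows$sequence[i]
        if (substr(cdna, p, p) != "T")
          cob_error(sprintf("%s: site %d lacks the preceding exonic T", sp, p),
                    "cobintron_site_consensus")
        if (substr(s, nchar(s), nchar(s)) != "G")
          cob_error(sprintf("%s: intron at %d does not end in G", sp, p),
                    "cobintron_site_consensus")
        gdna <- paste0(substr(gdna, 1L, p), s,
                       substr(gdna, p + 1L, nchar(gdna)))
      }
    }
    gene_record(sp, gdna = gdna, cdna = cdna,
                taxon_division = if (!is.null(divisions)) divisions[[sp]]
                                 else "Fungi")
  })
}

#' Simulate a complete catalogue with ground truth
#'
#' Runs the full generator: species tree, coding sequences, intron history,
#' and rendered gene records. Identical seed and configuration give
#' bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `catalogue` (a [new_catalogue()] of rendered records),
#'   `tree`, `cdnas`, and `truth` (list: `events`, `complements`,
#'   `families`, `site_pool`, `root_cds`).
#' @export
simulate_catalogue <- function(config = simulation_config()) {
  set.seed(config$seed)
  tree <- simulate_species_tree(config)
  root_cds <- random_root_cds(config$cds_length_codons + 1L)
  pool <- config$site_pool %||% default_site_pool(root_cds)
  if (!length(pool))
    cob_error("empty insertion-site pool", "cobintron_bad_config")
  cdnas <- evolve_coding_sequences(tree, config, root_cds = root_cds,
                                   frozen = pool)
  hist <- simulate_intron_history(tree, config, pool)
  records <- render_genomic_sequences(cdnas, hist$complements)
  cat <- new_catalogue(records,
                       provenance = list(source = "simulate_catalogue",
                                         seed = config$seed))
  list(catalogue = cat, tree = tree, cdnas = cdnas,
       truth = c(hist, list(site_pool = pool, root_cds = root_cds)))
}
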