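# Shared fixtures and independent oracles, built in code at test time.

# small, fast simulation defaults for unit tests
quick_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_taxa = 8L)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# map extracted introns onto true family ids via (species, insertion point)
truth_family_table <- function(catalogue, sim) {
  intr <- catalogue$introns
  tr <- sim$truth$complements
  tm <- stats::setNames(tr$family_id,
                        paste(tr$species_id, tr$insertion_point, sep = "@"))
  fid <- as.integer(tm[paste(intr$species_id, intr$insertion_point,
                             sep = "@")])
  asn <- catalogue$assignments
  data.frame(family_id = fid, intron_id = intr$intron_id,
             ref_codon = if (!is.null(asn))
               asn$ref_codon[match(intr$intron_id, asn$intron_id)]
             else NA_integer_)
}

# --- independent tiling oracle -----------------------------------------
# lexicographically best (by descending score sequence) pairwise
# non-overlapping HSP subset, by exhaustive enumeration; mirrors the
# documented tiling semantics with clipping disabled
oracle_tile <- function(hsps, len_a, len_b) {
  longer <- max(len_a, len_b)
  axis_q <- len_a >= len_b
  s <- if (axis_q) pmin(hsps$qstart, hsps$qend) else pmin(hsps$sstart, hsps$send)
  e <- if (axis_q) pmax(hsps$qstart, hsps$qend) else pmax(hsps$sstart, hsps$send)
  n <- nrow(hsps)
  best <- NULL; best_key <- ""
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(sel) > 1L) {
      ok <- TRUE
      for (i in sel) for (j in sel) if (i < j &&
          s[i] <= e[j] && s[j] <= e[i]) ok <- FALSE
      if (!ok) next
    }
    key <- paste(sprintf("%014.5f", sort(hsps$score[sel],
                                         decreasing = TRUE)),
                 collapse = ",")
    if (is.null(best) || key > best_key) { best <- sel; best_key <- key }
  }
  if (!length(best)) return(list(coverage = 0, mean_identity = 0,
                                 n_hsps_tiled = 0L))
  list(coverage = sum(e[best] - s[best] + 1L) / longer,
       mean_identity = 100 * sum(hsps$identities[best]) /
         sum(hsps$aligned_len[best]),
       n_hsps_tiled = length(best))
}

random_hsp_set <- function(n, len_a = 400L, len_b = 300L) {
  s <- sample.int(len_a - 30L, n)
  w <- sample(10:80, n, replace = TRUE)
  e <- pmin(s + w, len_a)
  al <- e - s + 1L
  id <- al - sample(0:3, n, replace = TRUE)   # keeps every score positive
  data.frame(qstart = s, qend = e, sstart = s, send = e,
             identities = id, aligned_len = al,
             score = 2 * id - 3 * (al - id) + seq_len(n) * 1e-3,
             bitscore = id, evalue = 1e-10)
}

# --- independent Dollo oracle ------------------------------------------
# exhaustive minimal-loss search: origin at the carriers' MRCA; losses can
# only sit on edges whose subtree holds no carrier; enumerate those edge
# subsets in order of size and return the first that explains every
# absent leaf below the origin
oracle_dollo <- function(present_leaves, tree) {
  tips <- tree$tip.label
  pres <- match(unique(present_leaves), tips)
  if (length(pres) == 1L)
    return(list(origin = pres, loss_branches = integer(0)))
  origin <- ape::getMRCA(tree, pres)
  below <- cobintron:::descendant_nodes(tree, origin)
  absent_tips <- setdiff(below[below <= length(tips)], pres)
  cand <- below[vapply(below, function(v) {
    lv <- cobintron:::leaves_below_or_self(tree, v)
    !any(match(lv, tips) %in% pres)
  }, logical(1))]
  if (!length(absent_tips))
    return(list(origin = origin, loss_branches = integer(0)))
  for (size in seq_along(cand)) {
    combs <- utils::combn(cand, size, simplify = FALSE)
    sols <- Filter(function(setv) {
      covered <- unique(unlist(lapply(setv, function(v)
        match(cobintron:::leaves_below_or_self(tree, v), tips))))
      all(absent_tips %in% covered)
    }, combs)
    if (length(sols))
      return(list(origin = origin, loss_branches = sort(sols[[1]])))
  }
  stop("oracle found no explanation")            # cannot happen
}

random_topology <- function(n) {
  # random binary tree via sequential attachment, unit branch lengths
  tr <- ape::rtree(n, br = NULL)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

printed_survey <- function() {
  # kingdom-level counts of the published cob-gene survey: genes per
  # division and intron-number classes (NA = partial gene, count unknown)
  expand <- function(div, n_genes, unknown, classes) {
    n_with <- unknown + sum(classes)
    data.frame(
      species_id = paste0(div, seq_len(n_genes)),
      taxon_division = div,
      n_introns = c(rep(NA_integer_, unknown),
                    rep(seq_along(classes), classes),
                    rep(0L, n_genes - n_with)))
  }
  rbind(expand("Fungi", 465, 11, c(19, 14, 10, 3, 4, 4, 4)),
        expand("Metazoa", 2062, 0, c(3, 0, 0, 0, 0, 0, 0)),
        expand("Plants", 440, 0, c(2, 3, 4, 0, 0, 0, 0)),
        expand("Protista", 309, 1, c(6, 2, 1, 1, 0, 0, 0)))
}

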