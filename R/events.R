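# Event inference: Dollo presence/absence reconstruction, lateral-gain
# flags from intron-vs-coding identity anomalies, minority-position
# transpositions, and recovery scoring against a simulated truth log.

#' Pairwise coding-sequence identity matrix
#'
#' Percent identity between every pair of coding sequences; used as the
#' relatedness proxy when flagging lateral gains. Equal-length sequences
#' are compared site-by-site, unequal lengths through a global alignment.
#'
#' @param records list of [gene_record()] (or a catalogue's `records`).
#' @return symmetric matrix of percent identities with unit diagonal
#'   (times 100).
#' @export
cdna_identity_matrix <- function(records) {
  ids <- sort(vapply(records, `[[`, character(1), "species_id"))
  seqs <- setNames(vapply(records, `[[`, character(1), "cdna"),
                   vapply(records, `[[`, character(1), "species_id"))[ids]
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    a <- seqs[[i]]; b <- seqs[[j]]
    pid <- if (nchar(a) == nchar(b)) hamming_identity(a, b)
           else Biostrings::pid(Biostrings::pairwiseAlignment(
             Biostrings::DNAString(a), Biostrings::DNAString(b),
             type = "global"))
    m[i, j] <- m[j, i] <- pid
  }
  m
}

#' Dollo parsimony reconstruction of one intron family
#'
#' A family is gained once, at the most recent common ancestor of the
#' leaves that carry it, and lost as often as needed: the loss set is the
#' minimal set of branches below the origin whose removal explains every
#' absent descendant — one loss on each maximal family-free subtree.
#'
#' @param present_leaves tip labels carrying the family (length >= 1).
#' @param tree rooted `phylo`.
#' @return list with `origin` (node id; the tip itself for a single
#'   leaf), `loss_branches` (child-node ids of the loss edges, sorted) and
#'   `n_losses`.
#' @export
dollo_reconstruct <- function(present_leaves, tree) {
  tips <- tree$tip.label
  if (!length(present_leaves) || !all(present_leaves %in% tips))
    cob_error("present_leaves must be a non-empty subset of the tips",
              "cobintron_bad_input")
  ntip <- length(tips)
  pres_id <- match(unique(present_leaves), tips)
  origin <- if (length(pres_id) == 1L) pres_id
            else ape::getMRCA(tree, pres_id)
  if (length(pres_id) == 1L)
    return(list(origin = origin, loss_branches = integer(0), n_losses = 0L))
  # has_present[v]: any present leaf in the subtree of v
  nn <- ntip + tree$Nnode
  has_present <- logical(nn)
  has_present[pres_id] <- TRUE
  e <- tree$edge
  for (k in ape::postorder(tree))
    has_present[e[k, 1]] <- has_present[e[k, 1]] | has_present[e[k, 2]]
  # losses: edges inside the origin clade whose child subtree is empty but
  # whose parent subtree is not
  below <- descendant_nodes(tree, origin)
  loss <- e[e[, 2] %in% below & !has_present[e[, 2]] & has_present[e[, 1]], 2]
  list(origin = origin, loss_branches = sort(loss),
       n_losses = length(loss))
}

# all nodes strictly below `node` (tips and internals)
descendant_nodes <- function(tree, node) {
  e <- tree$edge
  out <- integer(0)
  stack <- e[e[, 1] == node, 2]
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    out <- c(out, v)
    stack <- c(stack, e[e[, 1] == v, 2])
  }
  out
}

leaves_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  d <- descendant_nodes(tree, node)
  tree$tip.label[d[d <= ntip]]
}

#' Flag lateral intron gains within a family
#'
#' A member pair is flagged as a lateral transfer when the intron identity
#' of the pair exceeds the coding-sequence identity of the two species by
#' more than `delta` percentage points (introns should not be better
#' conserved than the coding gene under vertical descent) and the family
#' is absent from at least one species more closely related to either
#' member than the members are to each other (topological patchiness: an
#' intervening lineage lacks the family).
#'
#' @param members data frame of family members: `intron_id`, `species_id`.
#' @param intron_identities function or matrix giving percent identity for
#'   a member pair: either a matrix indexed by `intron_id`, or a function
#'   `(id_a, id_b) -> percent`.
#' @param cdna_identities species-by-species percent identity matrix from
#'   [cdna_identity_matrix()].
#' @param tree rooted `phylo` covering the species.
#' @param carriers species ids carrying any member of the family.
#' @param delta identity-anomaly threshold in percentage points.
#' @return data frame of flagged pairs with both identities and an
#'   evidence string (zero rows when nothing is flagged).
#' @export
flag_lateral_gains <- function(members, intron_identities, cdna_identities,
                               tree, carriers = unique(members$species_id),
                               delta = 5) {
  empty <- data.frame(kind = character(0), intron_a = character(0),
                      intron_b = character(0), species_a = character(0),
                      species_b = character(0), intron_identity = numeric(0),
                      cdna_identity = numeric(0), evidence = character(0))
  if (nrow(members) < 2L) return(empty)
  ii <- if (is.function(intron_identities)) intron_identities
        else function(a, b) intron_identities[a, b]
  depth <- node_topo_depth(tree)
  lacking <- setdiff(tree$tip.label, carriers)
  out <- list()
  pr <- t(combn(sort(members$intron_id), 2L))
  sp_of <- setNames(members$species_id, members$intron_id)
  for (k in seq_len(nrow(pr))) {
    a <- pr[k, 1]; b <- pr[k, 2]
    sa <- sp_of[[a]]; sb <- sp_of[[b]]
    if (sa == sb) next
    if (!sa %in% rownames(cdna_identities) ||
        !sb %in% rownames(cdna_identities)) {
      cob_warn(sprintf("no cdna identity for %s/%s; pair skipped", sa, sb))
      next
    }
    iid <- ii(a, b)
    cid <- cdna_identities[sa, sb]
    if (!(iid - cid > delta)) next
    if (!has_closer_lacking(tree, depth, sa, sb, lacking)) next
    out[[length(out) + 1L]] <- data.frame(
      kind = "lateral_gain", intron_a = a, intron_b = b,
      species_a = sa, species_b = sb,
      intron_identity = iid, cdna_identity = cid,
      evidence = sprintf(
        "intron identity %.1f%% vs cdna identity %.1f%% (delta %.1f); intervening lineage without the family",
        iid, cid, iid - cid))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# topological node depth (edges from root)
node_topo_depth <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  depth <- integer(nn)
  for (k in reorder_edges_preorder(tree))
    depth[tree$edge[k, 2]] <- depth[tree$edge[k, 1]] + 1L
  depth
}

# is some species in `lacking` more closely related to sa or sb than the
# two are to each other? (its MRCA with one of them lies below their MRCA)
has_closer_lacking <- function(tree, depth, sa, sb, lacking) {
  if (!length(lacking)) return(FALSE)
  ia <- match(sa, tree$tip.label); ib <- match(sb, tree$tip.label)
  mab <- ape::getMRCA(tree, c(ia, ib))
  for (x in lacking) {
    ix <- match(x, tree$tip.label)
    if (is.na(ix)) next
    if (depth[ape::getMRCA(tree, c(ia, ix))] > depth[mab] ||
        depth[ape::getMRCA(tree, c(ib, ix))] > depth[mab]) return(TRUE)
  }
  FALSE
}

#' Detect transpositions from multi-position families
#'
#' A family whose members occupy more than one reference position has been
#' relocated at least once; the minority-position members are reported as
#' transposed. The anchor (modal) position is the one with most members;
#' ties are broken toward the position closest to the median member
#' position, then toward the smaller position, so the call is
#' deterministic.
#'
#' @param families family table from [build_families()] with `ref_codon`.
#' @return data frame of transposition events: `family_id`, `intron_id`,
#'   `position`, `modal_position`, `evidence`.
#' @export
detect_transpositions <- function(families) {
  out <- list()
  for (f in unique(families$family_id)) {
    mem <- families[families$family_id == f & !is.na(families$ref_codon), ,
                    drop = FALSE]
    posv <- mem$ref_codon
    if (length(unique(posv)) < 2L) next
    tab <- table(posv)
    med <- median(posv)
    cand <- as.integer(names(tab))
    ord <- order(-as.integer(tab), abs(cand - med), cand)
    modal <- cand[ord[1]]
    moved <- mem[mem$ref_codon != modal, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      kind = "transposition", family_id = f, intron_id = moved$intron_id,
      position = moved$ref_codon, modal_position = modal,
      evidence = sprintf("family %d modal position %d; member at %d",
                         f, modal, moved$ref_codon))
  }
  if (!length(out))
    return(data.frame(kind = character(0), family_id = integer(0),
                      intron_id = character(0), position = integer(0),
                      modal_position = integer(0), evidence = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Infer the event log and score it against a simulation truth
#'
#' Composes the three detectors over every homologue family: Dollo origins
#' and losses from presence/absence, lateral-gain flags from identity
#' anomalies, and minority-position transpositions. When a truth log from
#' [simulate_catalogue()] is supplied, per-kind precision and recall are
#' computed: losses match on (family, loss branch); transfers match when a
#' flagged pair joins a leaf below the recipient branch with a leaf below
#' the donor branch of a true transfer of the same family; transpositions
#' match on (family, position). Inferred families are mapped onto truth
#' families by greatest member overlap.
#'
#' @param catalogue catalogue with introns and assignments.
#' @param tree rooted `phylo` over the catalogue species.
#' @param families family table from [build_families()].
#' @param intron_identities optional percent-identity source for member
#'   pairs (matrix by intron_id or function); computed from the intron
#'   sequences when `NULL`.
#' @param truth optional truth list (needs `events`, `complements`).
#' @param delta lateral-gain anomaly threshold (percentage points).
#' @return list with `origins`, `losses`, `lateral_gains`,
#'   `transpositions` data frames, and `recovery` (per-kind precision /
#'   recall) when truth is given.
#' @export
recover_events <- function(catalogue, tree, families,
                           intron_identities = NULL, truth = NULL,
                           delta = 5) {
  asn <- catalogue$assignments
  intr <- catalogue$introns
  sp_of <- setNames(intr$species_id, intr$intron_id)
  if (is.null(intron_identities)) {
    seqs <- setNames(intr$sequence, intr$intron_id)
    intron_identities <- function(a, b) {
      if (nchar(seqs[[a]]) == nchar(seqs[[b]]))
        hamming_identity(seqs[[a]], seqs[[b]])
      else Biostrings::pid(Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[[a]]), Biostrings::DNAString(seqs[[b]]),
        type = "local"))
    }
  }
  cid <- cdna_identity_matrix(catalogue$records)

  origins <- list(); losses <- list(); lats <- list()
  for (f in unique(families$family_id)) {
    mem <- families[families$family_id == f, , drop = FALSE]
    carriers <- sort(unique(sp_of[mem$intron_id]))
    carriers <- intersect(carriers, tree$tip.label)
    if (!length(carriers)) next
    rec <- dollo_reconstruct(carriers, tree)
    origins[[length(origins) + 1L]] <- data.frame(
      kind = "origin", family_id = f, node = rec$origin,
      clade = paste(sort(leaves_below_or_self(tree, rec$origin)),
                    collapse = ","))
    if (rec$n_losses)
      losses[[length(losses) + 1L]] <- data.frame(
        kind = "loss", family_id = f, branch_child = rec$loss_branches,
        clade = vapply(rec$loss_branches, function(v)
          paste(sort(leaves_below_or_self(tree, v)), collapse = ","),
          character(1)))
    memdf <- data.frame(intron_id = mem$intron_id,
                        species_id = unname(sp_of[mem$intron_id]))
    lg <- flag_lateral_gains(memdf, intron_identities, cid, tree,
                             carriers = carriers, delta = delta)
    if (nrow(lg)) {
      lg$family_id <- f
      lats[[length(lats) + 1L]] <- lg
    }
  }
  fam_asn <- families
  if (!"ref_codon" %in% names(fam_asn) && !is.null(asn))
    fam_asn$ref_codon <- asn$ref_codon[match(fam_asn$intron_id,
                                             asn$intron_id)]
  transp <- detect_transpositions(fam_asn)

  res <- list(
    origins = bind_or_empty(origins, c("kind", "family_id", "node", "clade")),
    losses = bind_or_empty(losses,
                           c("kind", "family_id", "branch_child", "clade")),
    lateral_gains = if (length(lats)) do.call(rbind, lats) else
      flag_lateral_gains(data.frame(intron_id = character(0),
                                    species_id = character(0)),
                         function(a, b) 0, cid, tree),
    transpositions = transp)
  if (!is.null(truth))
    res$recovery <- score_recovery(res, truth, tree, families, intr)
  res
}

leaves_below_or_self <- function(tree, node) {
  if (node <= length(tree$tip.label)) tree$tip.label[node]
  else leaves_below(tree, node)
}

bind_or_empty <- function(lst, cols) {
  if (length(lst)) {
    out <- do.call(rbind, lst); rownames(out) <- NULL; return(out)
  }
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  out
}

# map inferred family ids onto truth family ids by member overlap; with
# simulated catalogues intron_id encodes the true family via the truth
# complements table
truth_family_map <- function(families, truth_members) {
  vapply(split(families$intron_id, families$family_id), function(mem) {
    tf <- truth_members[mem]
    tf <- tf[!is.na(tf)]
    if (!length(tf)) return(NA_integer_)
    as.integer(names(sort(table(tf), decreasing = TRUE))[1])
  }, integer(1))
}

score_recovery <- function(res, truth, tree, families, introns) {
  # truth family of each extracted intron, keyed species @ insertion point
  comp <- truth$complements
  key <- function(sp, p) paste(sp, p, sep = "@")
  tm <- setNames(comp$family_id, key(comp$species_id, comp$insertion_point))
  tm_intron <- setNames(tm[key(introns$species_id, introns$insertion_point)],
                        introns$intron_id)
  fam_map <- truth_family_map(families, tm_intron)

  prec_rec <- function(n_match_flag, n_flag, n_match_truth, n_truth) {
    c(precision = if (n_flag) n_match_flag / n_flag else NA_real_,
      recall = if (n_truth) n_match_truth / n_truth else NA_real_,
      n_flag_matched = n_match_flag, n_flagged = n_flag,
      n_truth_matched = n_match_truth, n_truth = n_truth)
  }

  ev <- truth$events
  out <- list()

  # ---- losses: match on (truth family, loss clade) ----
  tl <- ev[ev$kind == "loss", , drop = FALSE]
  tl_clade <- vapply(seq_len(nrow(tl)), function(i)
    paste(sort(leaves_below_or_self(tree, tl$branch_child[i])),
          collapse = ","), character(1))
  tl_key <- paste(tl$family_id, tl_clade)
  il <- res$losses
  il_key <- if (nrow(il))
    paste(fam_map[as.character(il$family_id)], il$clade) else character(0)
  # identifiable stratum: the family is retained by lineages bracketing the
  # loss branch -- in the sibling subtree and outside the parent's subtree
  # (otherwise the loss is provably absorbed into a merged loss or into the
  # origin placement, and no presence/absence method can place it)
  e <- tree$edge
  strat <- if (nrow(tl)) vapply(seq_len(nrow(tl)), function(i) {
    fid <- tl$family_id[i]; v <- tl$branch_child[i]
    csp <- comp$species_id[comp$family_id == fid]
    below <- leaves_below_or_self(tree, v)
    if (any(csp %in% below)) return(FALSE)        # regained below: not a clean loss
    u <- e[e[, 2] == v, 1]
    sibs <- setdiff(e[e[, 1] == u, 2], v)
    sib_leaves <- unlist(lapply(sibs, leaves_below_or_self, tree = tree))
    parent_leaves <- leaves_below_or_self(tree, u)
    any(csp %in% sib_leaves) && any(!csp %in% parent_leaves)
  }, logical(1)) else logical(0)
  out$loss <- prec_rec(sum(il_key %in% tl_key), length(il_key),
                       sum(tl_key[strat] %in% il_key), sum(strat))

  # ---- transfers: flagged pair joins recipient and donor descendants ----
  tt <- ev[ev$kind == "transfer", , drop = FALSE]
  lg <- res$lateral_gains
  rec_leaves <- lapply(seq_len(nrow(tt)), function(j)
    leaves_below_or_self(tree, tt$branch_child[j]))
  # a flagged pair explains a transfer when it joins a carrier inside the
  # recipient clade with a carrier outside it (the donor copy is shared
  # vertically by the donor's relatives) for the same truth family
  lg_fam <- if (nrow(lg)) fam_map[as.character(lg$family_id)] else integer(0)
  flag_hit <- logical(nrow(lg)); truth_hit <- logical(nrow(tt))
  if (nrow(lg) && nrow(tt))
    for (i in seq_len(nrow(lg))) for (j in seq_len(nrow(tt))) {
      if (!identical(lg_fam[[i]], tt$family_id[j])) next
      sa <- lg$species_a[i]; sb <- lg$species_b[i]
      hit <- (sa %in% rec_leaves[[j]] && !sb %in% rec_leaves[[j]]) ||
        (sb %in% rec_leaves[[j]] && !sa %in% rec_leaves[[j]])
      if (hit) { flag_hit[i] <- TRUE; truth_hit[j] <- TRUE }
    }
  # visible stratum: recipient copy and an outside copy each reach a leaf
  visible <- if (nrow(tt)) vapply(seq_len(nrow(tt)), function(j) {
    csp <- comp$species_id[comp$family_id == tt$family_id[j]]
    any(csp %in% rec_leaves[[j]]) && any(!csp %in% rec_leaves[[j]])
  }, logical(1)) else logical(0)
  out$transfer <- prec_rec(sum(flag_hit), nrow(lg),
                           sum(truth_hit[visible]), sum(visible))

  # ---- transpositions: match on (truth family, new position codon) ----
  tp <- ev[ev$kind == "transposition", , drop = FALSE]
  it <- res$transpositions
  it_key <- if (nrow(it))
    paste(fam_map[as.character(it$family_id)], it$position) else character(0)
  tp_key <- if (nrow(tp)) paste(tp$family_id, tp$codon) else character(0)
  # visible: some leaf still carries the family at the new position
  tp_vis <- if (nrow(tp)) vapply(seq_len(nrow(tp)), function(j)
    any(comp$family_id == tp$family_id[j] &
          ceiling(comp$insertion_point / 3) == tp$codon[j]), logical(1))
    else logical(0)
  out$transposition <- prec_rec(sum(it_key %in% tp_key), length(it_key),
                                sum(tp_key[tp_vis] %in% it_key),
                                sum(tp_vis))
  do.call(rbind, out)
}
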