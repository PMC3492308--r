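# Pairwise intron homology by local-alignment HSP tiling, and homologue
# families as connected components of the reciprocal homology graph.

#' Homology thresholds
#'
#' Defaults follow the catalogue-wide criteria: BLASTN E-value cutoff
#' 1e-05, tiled coverage over the longer intron > 0.30, tiled average
#' identity > 80 percent, criteria required in both query/subject
#' orientations ("strict" reciprocity) or in at least one ("any").
#'
#' @param evalue_cutoff maximum HSP expectation value.
#' @param min_coverage coverage threshold (exclusive).
#' @param min_identity identity threshold as a fraction (exclusive).
#' @param reciprocal `"strict"` or `"any"`.
#' @return a named list of thresholds.
#' @export
homology_thresholds <- function(evalue_cutoff = 1e-5, min_coverage = 0.30,
                                min_identity = 0.80,
                                reciprocal = c("strict", "any")) {
  stopifnot(evalue_cutoff > 0, min_coverage > 0, min_coverage <= 1,
            min_identity > 0, min_identity <= 1)
  list(evalue_cutoff = evalue_cutoff, min_coverage = min_coverage,
       min_identity = min_identity, reciprocal = match.arg(reciprocal))
}

#' Find high-scoring segment pairs between two sequences
#'
#' The default engine shells out to NCBI `blastn` (`-task blastn`: word
#' size 11, match +2 / mismatch -3, gap open 5 / extend 2 — the classic
#' BLASTN defaults) in pairwise `-subject` mode, so E-values use the
#' pairwise `m * n` search space. The `"sw"` engine repeats gapped
#' Smith-Waterman (same scoring) with masking of previously reported
#' segments, scoring significance by Karlin-Altschul statistics with a
#' numerically solved lambda; it needs no external binary but is slower
#' and reports plus-strand hits only.
#'
#' @param a,b nucleotide sequences (query, subject).
#' @param evalue_cutoff report HSPs with expectation value at or below
#'   this.
#' @param engine `"blastn"` or `"sw"`.
#' @param word_size blastn seed word size.
#' @param max_hsps cap on reported HSPs.
#' @return data frame of HSPs sorted by score descending: `qstart`,
#'   `qend`, `sstart`, `send` (1-based inclusive; `sstart > send` marks a
#'   minus-strand hit), `identities`, `aligned_len`, `score`, `bitscore`,
#'   `evalue`.
#' @export
find_hsps <- function(a, b, evalue_cutoff = 1e-5,
                      engine = c("blastn", "sw"), word_size = 11L,
                      max_hsps = 50L) {
  engine <- match.arg(engine)
  if (!nzchar(a) || !nzchar(b))
    cob_error("find_hsps needs two non-empty sequences", "cobintron_bad_input")
  if (engine == "blastn") blastn_hsps(a, b, evalue_cutoff, word_size, max_hsps)
  else sw_hsps(a, b, evalue_cutoff, max_hsps)
}

empty_hsps <- function() {
  data.frame(qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), identities = integer(0),
             aligned_len = integer(0), score = numeric(0),
             bitscore = numeric(0), evalue = numeric(0))
}

blastn_hsps <- function(a, b, evalue_cutoff, word_size, max_hsps) {
  if (Sys.which("blastn") == "")
    cob_error("blastn not found on the PATH; use engine = \"sw\"",
              "cobintron_no_blastn")
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  of <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(qf, sf, of)))
  writeLines(c(">q", wrap_seq(a)), qf)
  writeLines(c(">s", wrap_seq(b)), sf)
  status <- system2("blastn",
    c("-task", "blastn", "-query", qf, "-subject", sf,
      "-word_size", word_size, "-evalue", format(evalue_cutoff),
      "-max_hsps", max_hsps,
      "-outfmt", shQuote("6 qstart qend sstart send nident length score bitscore evalue")),
    stdout = of, stderr = FALSE)
  if (status != 0L)
    cob_error(sprintf("blastn exited with status %d", status),
              "cobintron_blastn_failed")
  lines <- readLines(of, warn = FALSE)
  if (!length(lines)) return(empty_hsps())
  m <- read.table(text = lines, sep = "\t",
                  col.names = c("qstart", "qend", "sstart", "send",
                                "identities", "aligned_len", "score",
                                "bitscore", "evalue"))
  m <- m[order(-m$score, m$qstart), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Karlin-Altschul lambda for match/mismatch scoring with uniform base
# composition: solve sum_ij p_i p_j exp(lambda s_ij) = 1
ka_lambda <- function(match = 2, mismatch = -3) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

sw_hsps <- function(a, b, evalue_cutoff, max_hsps,
                    match = 2, mismatch = -3, gap_open = 5, gap_extend = 2,
                    K = 0.41) {
  lambda <- ka_lambda(match, mismatch)
  mn <- as.numeric(nchar(a)) * nchar(b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  mat["N", ] <- mismatch; mat[, "N"] <- mismatch
  qa <- a; sb <- b
  out <- list()
  for (i in seq_len(max_hsps)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qa), Biostrings::DNAString(sb),
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "local")
    score <- Biostrings::score(aln)
    evalue <- K * mn * exp(-lambda * score)
    if (score <= 0 || evalue > evalue_cutoff) break
    qs <- Biostrings::start(Biostrings::pattern(aln))
    qe <- Biostrings::end(Biostrings::pattern(aln))
    ss <- Biostrings::start(Biostrings::subject(aln))
    se <- Biostrings::end(Biostrings::subject(aln))
    pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
    ps <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
    out[[i]] <- data.frame(qstart = qs, qend = qe, sstart = ss, send = se,
                           identities = sum(pa == ps & pa != "-"),
                           aligned_len = length(pa),
                           score = score,
                           bitscore = (lambda * score - log(K)) / log(2),
                           evalue = evalue)
    # mask reported spans so further passes find other segments
    substr(qa, qs, qe) <- paste(rep("N", qe - qs + 1L), collapse = "")
    substr(sb, ss, se) <- paste(rep("N", se - ss + 1L), collapse = "")
  }
  if (!length(out)) return(empty_hsps())
  m <- do.call(rbind, out)
  m <- m[order(-m$score, m$qstart), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Tile HSPs and compute coverage and mean identity
#'
#' Greedy tiling by descending score on the longer sequence's axis: an HSP
#' is accepted only if, after clipping an overlap of at most `max_clip`
#' columns, it overlaps no previously tiled column. Coverage is the summed
#' tiled segment length divided by the longer sequence's length; mean
#' identity is `100 * sum(identities) / sum(aligned_len)` over the tiled
#' HSPs (clipped HSPs contribute proportionally).
#'
#' @param hsps HSP data frame from [find_hsps()].
#' @param len_a,len_b query and subject lengths.
#' @param max_clip largest overlap clipped rather than rejected (nt).
#' @return list: `coverage`, `mean_identity` (percent), `n_hsps_tiled`.
#' @export
tile_and_score <- function(hsps, len_a, len_b, max_clip = 10L) {
  longer <- max(len_a, len_b)
  if (is.null(hsps) || !nrow(hsps))
    return(list(coverage = 0, mean_identity = 0, n_hsps_tiled = 0L))
  axis_q <- len_a >= len_b
  s0 <- if (axis_q) pmin(hsps$qstart, hsps$qend) else pmin(hsps$sstart, hsps$send)
  e0 <- if (axis_q) pmax(hsps$qstart, hsps$qend) else pmax(hsps$sstart, hsps$send)
  ord <- order(-hsps$score, -hsps$identities, s0)
  occupied <- logical(longer)
  tot_len <- 0L; tot_ident <- 0; tot_cols <- 0; n <- 0L
  for (i in ord) {
    s <- s0[i]; e <- e0[i]
    free <- which(!occupied[s:e])
    ov <- (e - s + 1L) - length(free)
    if (!length(free) || ov > max_clip) next
    if (ov > 0L && any(diff(free) != 1L)) next   # clip must keep one segment
    ns <- s + free[1] - 1L; ne <- s + free[length(free)] - 1L
    frac <- (ne - ns + 1L) / (e - s + 1L)
    tot_len <- tot_len + (ne - ns + 1L)
    tot_ident <- tot_ident + hsps$identities[i] * frac
    tot_cols <- tot_cols + hsps$aligned_len[i] * frac
    occupied[ns:ne] <- TRUE
    n <- n + 1L
  }
  if (n == 0L) return(list(coverage = 0, mean_identity = 0, n_hsps_tiled = 0L))
  list(coverage = tot_len / longer,
       mean_identity = 100 * tot_ident / tot_cols,
       n_hsps_tiled = n)
}

#' Decide homology from two orientations of tiled statistics
#'
#' Both (reciprocal `"strict"`, the default) or at least one
#' (`"any"`) orientation must exceed the coverage and identity
#' thresholds strictly.
#'
#' @param stats_ab,stats_ba [tile_and_score()] results for the two
#'   query/subject orientations.
#' @param thresholds a [homology_thresholds()].
#' @return logical flag; symmetric in its first two arguments.
#' @export
homologous <- function(stats_ab, stats_ba,
                       thresholds = homology_thresholds()) {
  pass <- function(s) s$coverage > thresholds$min_coverage &&
    s$mean_identity > 100 * thresholds$min_identity
  if (thresholds$reciprocal == "strict") pass(stats_ab) && pass(stats_ba)
  else pass(stats_ab) || pass(stats_ba)
}

#' Pairwise homology statistics over a set of introns
#'
#' Computes HSPs for every ordered pair, tiles them with
#' [tile_and_score()], and applies [homologous()] to each unordered pair.
#' With the blastn engine all comparisons run as a single all-vs-all
#' search whose hits are re-scored for the pairwise `m * n` search space
#' from their bit scores (`E = m * n * 2^-S'`), so the expectation cutoff
#' matches the pairwise convention rather than a database-wide one.
#' Output order is canonical (sorted intron ids), so results do not
#' depend on input order.
#'
#' @param introns intron table (needs `intron_id`, `sequence`).
#' @param thresholds a [homology_thresholds()].
#' @param engine,max_clip passed to [find_hsps()] / [tile_and_score()].
#' @return data frame, one row per unordered pair: ids, coverage and
#'   identity in both orientations, `reciprocal_ok` and `homologous`.
#' @export
pairwise_homology <- function(introns, thresholds = homology_thresholds(),
                              engine = c("blastn", "sw"), max_clip = 10L) {
  engine <- match.arg(engine)
  ids <- sort(introns$intron_id)
  seqs <- setNames(introns$sequence, introns$intron_id)[ids]
  if (length(ids) < 2L)
    return(data.frame(intron_a = character(0), intron_b = character(0),
                      coverage_ab = numeric(0), identity_ab = numeric(0),
                      coverage_ba = numeric(0), identity_ba = numeric(0),
                      reciprocal_ok = logical(0), homologous = logical(0)))
  hsp_of <- if (engine == "blastn")
    batched_hsps(seqs, thresholds$evalue_cutoff)
  else NULL
  get_hsps <- function(qa, sb) {
    if (!is.null(hsp_of)) hsp_of[[paste(qa, sb, sep = "\r")]] %||% empty_hsps()
    else find_hsps(seqs[[qa]], seqs[[sb]], thresholds$evalue_cutoff, engine)
  }
  pairs <- t(combn(ids, 2L))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    ia <- pairs[k, 1]; ib <- pairs[k, 2]
    la <- nchar(seqs[[ia]]); lb <- nchar(seqs[[ib]])
    ab <- tile_and_score(get_hsps(ia, ib), la, lb, max_clip)
    ba <- tile_and_score(get_hsps(ib, ia), lb, la, max_clip)
    data.frame(intron_a = ia, intron_b = ib,
               coverage_ab = ab$coverage, identity_ab = ab$mean_identity,
               coverage_ba = ba$coverage, identity_ba = ba$mean_identity,
               reciprocal_ok = homologous(ab, ba, thresholds) &&
                 homologous(ba, ab, thresholds),
               homologous = homologous(ab, ba, thresholds))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# one all-vs-all blastn run; E-values re-scored to the pairwise search
# space from the bit score (no edge-length correction; deterministic)
batched_hsps <- function(seqs, evalue_cutoff, word_size = 11L) {
  if (Sys.which("blastn") == "")
    cob_error("blastn not found on the PATH; use engine = \"sw\"",
              "cobintron_no_blastn")
  fa <- tempfile(fileext = ".fa"); of <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fa, of)))
  con <- file(fa, "w")
  for (id in names(seqs))
    writeLines(c(paste0(">", id), wrap_seq(seqs[[id]])), con)
  close(con)
  status <- system2("blastn",
    c("-task", "blastn", "-query", fa, "-subject", fa,
      "-word_size", word_size, "-evalue", "0.01", "-max_hsps", 50L,
      "-outfmt",
      shQuote("6 qseqid sseqid qstart qend sstart send nident length score bitscore evalue")),
    stdout = of, stderr = FALSE)
  if (status != 0L)
    cob_error(sprintf("blastn exited with status %d", status),
              "cobintron_blastn_failed")
  lines <- readLines(of, warn = FALSE)
  if (!length(lines)) return(list())
  m <- read.table(text = lines, sep = "\t",
                  col.names = c("qseqid", "sseqid", "qstart", "qend",
                                "sstart", "send", "identities",
                                "aligned_len", "score", "bitscore",
                                "evalue"))
  m <- m[m$qseqid != m$sseqid, , drop = FALSE]
  if (!nrow(m)) return(list())
  lens <- vapply(seqs, nchar, integer(1))
  m$evalue <- lens[m$qseqid] * lens[m$sseqid] * 2^(-m$bitscore)
  m <- m[m$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(m)) return(list())
  m <- m[order(-m$score, m$qstart), , drop = FALSE]
  split(m[, setdiff(names(m), c("qseqid", "sseqid"))],
        paste(m$qseqid, m$sseqid, sep = "\r"))
}

#' Build homologue families
#'
#' Families are the connected components of the undirected homology graph;
#' introns without any homologue form singleton families (retained, marked
#' by `n_members == 1`). Family ids are assigned deterministically by the
#' smallest member reference position, then by member name.
#'
#' @param introns intron table (all introns to be partitioned).
#' @param pairs pairwise table from [pairwise_homology()] (or any data
#'   frame with `intron_a`, `intron_b`, `homologous`).
#' @param assignments optional assignments table supplying `ref_codon` and
#'   `name` for ordering and reporting.
#' @return data frame: `family_id`, `intron_id`, `n_members`, plus
#'   `ref_codon` and `name` when assignments are given.
#' @export
build_families <- function(introns, pairs, assignments = NULL) {
  ids <- sort(introns$intron_id)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  e <- pairs[pairs$homologous, c("intron_a", "intron_b"), drop = FALSE]
  if (nrow(e))
    g <- igraph::add_edges(g, t(as.matrix(e)))
  comp <- igraph::components(g)$membership
  fam <- split(names(comp), comp)
  pos <- setNames(rep(NA_integer_, length(ids)), ids)
  nm <- setNames(ids, ids)
  if (!is.null(assignments)) {
    m <- match(ids, assignments$intron_id)
    pos[] <- assignments$ref_codon[m]
    has_name <- !is.na(m) & !is.na(assignments$name[m])
    nm[has_name] <- assignments$name[m][has_name]
  }
  key <- vapply(fam, function(members)
    sprintf("%09d|%s", min(c(pos[members], .Machine$integer.max - 1L),
                           na.rm = TRUE),
            min(nm[members])), character(1))
  fam <- fam[order(key)]
  out <- do.call(rbind, lapply(seq_along(fam), function(i)
    data.frame(family_id = i, intron_id = sort(fam[[i]]),
               n_members = length(fam[[i]]))))
  if (!is.null(assignments)) {
    m <- match(out$intron_id, assignments$intron_id)
    out$ref_codon <- assignments$ref_codon[m]
    out$name <- assignments$name[m]
  }
  rownames(out) <- NULL
  out
}
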