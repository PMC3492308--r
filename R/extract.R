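# Intron extraction: decompose each genomic sequence into exons and introns
# by comparison with the spliced coding sequence.

#' Extract introns from a gene record
#'
#' Decomposes `gdna` into exons and introns by greedy maximal anchoring of
#' the cdna: exons are matched left to right as maximal exact substrings of
#' the gdna, and the gaps between consecutive exons are the introns. When
#' identical bases repeated across an exon/intron boundary admit several
#' equivalent decompositions (a junction ambiguity), the placement whose
#' intron ends in G with a preceding exonic T (the group I splice
#' consensus) is chosen; if no placement, or more than one, qualifies, the
#' leftmost intron start is used and `placement_ambiguous` is set.
#'
#' Insertion points are coding coordinates: the intron lies immediately
#' after coding nucleotide `insertion_point` (1-based).
#'
#' With `max_mismatches_per_exon > 0`, isolated mismatches between cdna and
#' exon (database sequence noise) are tolerated while extending an exon,
#' provided the match resumes immediately afterwards.
#'
#' @param record a [gene_record()].
#' @param max_mismatches_per_exon mismatches tolerated per exon (default 0:
#'   same-isolate gDNA/cDNA pairs are expected to agree exactly).
#' @return data frame with one row per intron: `intron_id`, `species_id`,
#'   `ordinal` (1-based 5' to 3'), `insertion_point`, `length`, `sequence`,
#'   `upstream_exon_base`, `terminal_base`, `upstream_flank`,
#'   `downstream_flank` (up to 5 nt each side), `placement_ambiguous`.
#' @export
#' @examples
#' r <- gene_record("sp", gdna = "ATGAAATTCCCGTTTGGATAA",
#'                        cdna = "ATGAAATTTGGATAA")
#' extract_introns(r)
extract_introns <- function(record, max_mismatches_per_exon = 0L) {
  gdna <- record$gdna; cdna <- record$cdna
  rg <- charToRaw(gdna); rc <- charToRaw(cdna)
  nG <- length(rg); nC <- length(rc)
  deepest <- 1L   # furthest coding offset reached, for error reporting
  budget <- 20000L   # backtracking budget; exhausted only on pathological input

  # Recursive descent with backtracking. Exons are matched maximally; at a
  # mismatch the next exon start is sought by anchoring a prefix of the
  # remaining cdna in the remaining gdna, shrinking the anchor when exons
  # are shorter than it (real cob exons go down to ~11 nt).
  parse <- function(pos_c, pos_g) {
    budget <<- budget - 1L
    if (budget < 0L)
      cob_error(sprintf(
        "%s: decomposition search exhausted (ambiguous or repetitive input)",
        record$species_id), "cobintron_extraction_failure")
    m <- match_run(rc, pos_c, rg, pos_g, max_mismatches_per_exon)
    pos_c <- pos_c + m; pos_g <- pos_g + m
    if (pos_c > nC) {
      if (pos_g <= nG) return(NULL)              # trailing genomic residue
      return(list())
    }
    deepest <<- max(deepest, pos_c)
    if (pos_c == 1L) return(NULL)                # gene must start with exon
    rem <- nC - pos_c + 1L
    # anchors never drop below 8 nt: real cob exons are >= ~11 nt, and
    # shorter anchors admit spurious matches all over a 10 kb gene
    for (k in unique(pmin(rem, c(20L, 12L, 8L)))) {
      anchor <- substr(cdna, pos_c, pos_c + k - 1L)
      occ <- find_all(anchor, gdna, from = pos_g + 1L)
      for (g2 in head(occ, 50L)) {
        rest <- parse(pos_c, g2)
        if (!is.null(rest))
          return(c(list(c(s = pos_g, e = g2 - 1L, p_right = pos_c - 1L)),
                   rest))
      }
      if (length(occ)) break   # anchors matched but no parse: backtrack up
    }
    NULL
  }

  raw_introns <- parse(1L, 1L)
  if (is.null(raw_introns))
    cob_error(sprintf(
      "%s: cdna not decomposable within gdna (first failing coding offset %d)",
      record$species_id, deepest), "cobintron_extraction_failure")
  canonicalize_introns(record, raw_introns)
}

# maximal match length of cdna[ic..] against gdna[ig..], optionally reading
# through isolated mismatches when the match resumes for >= 10 nt
match_run <- function(rc, ic, rg, ig, budget = 0L) {
  total <- 0L
  repeat {
    m <- lcp_len(rc, ic + total, rg, ig + total)
    total <- total + m
    if (budget <= 0L) return(total)
    rem <- min(length(rc) - (ic + total), length(rg) - (ig + total))
    if (rem < 0L) return(total)
    nxt <- lcp_len(rc, ic + total + 1L, rg, ig + total + 1L)
    if (nxt >= min(10L, rem)) {
      total <- total + 1L
      budget <- budget - 1L
    } else return(total)
  }
}

canonicalize_introns <- function(record, raw_introns) {
  gdna <- record$gdna
  nG <- nchar(gdna)
  prev_p <- 0L
  rows <- lapply(seq_along(raw_introns), function(i) {
    x <- raw_introns[[i]]
    s <- x[["s"]]; e <- x[["e"]]; p_right <- x[["p_right"]]
    # enumerate equivalent left shifts of the boundary
    t_max <- 0L
    while (s - t_max - 1L >= 2L &&
           p_right - t_max - 1L > prev_p &&
           substr(gdna, s - t_max - 1L, s - t_max - 1L) ==
             substr(gdna, e - t_max, e - t_max))
      t_max <- t_max + 1L
    ts <- 0:t_max
    ambiguous <- FALSE
    if (t_max > 0L) {
      qual <- ts[substring(gdna, e - ts, e - ts) == "G" &
                   substring(gdna, s - ts - 1L, s - ts - 1L) == "T"]
      if (length(qual) == 1L) t <- qual
      else { t <- t_max; ambiguous <- TRUE }
    } else t <- 0L
    s <- s - t; e <- e - t
    p <- p_right - t
    prev_p <<- p
    data.frame(
      species_id = record$species_id, ordinal = i,
      insertion_point = p, length = e - s + 1L,
      sequence = substr(gdna, s, e),
      upstream_exon_base = substr(gdna, s - 1L, s - 1L),
      terminal_base = substr(gdna, e, e),
      upstream_flank = substr(gdna, max(1L, s - 5L), s - 1L),
      downstream_flank = substr(gdna, e + 1L, min(nG, e + 5L)),
      placement_ambiguous = ambiguous)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(species_id = character(0), ordinal = integer(0),
                         insertion_point = integer(0), length = integer(0),
                         sequence = character(0),
                         upstream_exon_base = character(0),
                         terminal_base = character(0),
                         upstream_flank = character(0),
                         downstream_flank = character(0),
                         placement_ambiguous = logical(0))
  out <- cbind(intron_id = sprintf("%s.i%d", out$species_id, out$ordinal),
               out)
  rownames(out) <- NULL
  out
}

#' Extract introns for every record of a catalogue
#'
#' @param catalogue a [new_catalogue()].
#' @param ... passed to [extract_introns()].
#' @return the catalogue with its intron table filled in.
#' @export
extract_all_introns <- function(catalogue, ...) {
  tabs <- lapply(catalogue$records, extract_introns, ...)
  introns <- do.call(rbind, tabs)
  rownames(introns) <- NULL
  new_catalogue(catalogue$records, introns = introns,
                assignments = catalogue$assignments,
                provenance = catalogue$provenance)
}

#' Check the group I splice consensus of an intron
#'
#' Pure predicate report: does the intron end in G, and is the exonic base
#' immediately upstream a T?
#'
#' @param intron one row of the intron table (or a list with `sequence` and
#'   `upstream_exon_base`).
#' @return list with logical `ends_in_G` and `preceded_by_T`.
#' @export
validate_splice_consensus <- function(intron) {
  s <- intron$sequence
  list(ends_in_G = substr(s, nchar(s), nchar(s)) == "G",
       preceded_by_T = intron$upstream_exon_base == "T")
}
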