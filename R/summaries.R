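# Descriptive tables: intron frequencies by taxon division, the position
# distribution, and the codon-143 QoI-constraint report.

#' Intron frequency table by taxon division
#'
#' One row per division plus a total row. `n_introns` of `NA` marks a
#' partial gene whose intron count is unknown; such genes count as
#' intron-bearing in the `unknown` class. Percentages are
#' `100 * count / n_genes` of the row's own division, rounded half-up to
#' two decimals. Genes without a division label are gathered into an
#' `unclassified` row with a warning.
#'
#' @param genes data frame with one row per gene: `species_id`,
#'   `taxon_division`, `n_introns` (integer or `NA`). Conveniently built
#'   from a catalogue with [catalogue_gene_table()].
#' @param max_class intron-number classes are 1..`max_class` (larger
#'   counts are pooled into the top class).
#' @return data frame: `taxon_division`, `n_genes`, `n_with_introns`,
#'   `unknown`, `i1`..`i<max_class>` counts, matching `pct_*` columns and
#'   `pct_total`.
#' @export
taxon_frequency_table <- function(genes, max_class = 7L) {
  genes <- as.data.frame(genes)
  if (any(is.na(genes$taxon_division) | !nzchar(genes$taxon_division))) {
    cob_warn("genes without a division label assigned to 'unclassified'")
    genes$taxon_division[is.na(genes$taxon_division) |
                           !nzchar(genes$taxon_division)] <- "unclassified"
  }
  divisions <- unique(genes$taxon_division)
  mk_row <- function(div, sub) {
    n_genes <- nrow(sub)
    with_introns <- sub$n_introns > 0L | is.na(sub$n_introns)
    nw <- sum(with_introns)
    unknown <- sum(is.na(sub$n_introns))
    cls <- pmin(sub$n_introns[!is.na(sub$n_introns) & sub$n_introns > 0L],
                max_class)
    counts <- tabulate(cls, nbins = max_class)
    pct <- function(k) round_half_up(100 * k / n_genes, 2)
    row <- data.frame(taxon_division = div, n_genes = n_genes,
                      n_with_introns = nw, unknown = unknown)
    for (i in seq_len(max_class)) row[[paste0("i", i)]] <- counts[i]
    row$pct_unknown <- pct(unknown)
    for (i in seq_len(max_class)) row[[paste0("pct_i", i)]] <- pct(counts[i])
    row$pct_total <- pct(nw)
    row
  }
  rows <- lapply(divisions, function(d)
    mk_row(d, genes[genes$taxon_division == d, , drop = FALSE]))
  rows[[length(rows) + 1L]] <- mk_row("Total", genes)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene intron counts of a catalogue
#'
#' @param catalogue catalogue with extracted introns.
#' @return data frame `species_id`, `taxon_division`, `n_introns`, ready
#'   for [taxon_frequency_table()].
#' @export
catalogue_gene_table <- function(catalogue) {
  counts <- table(catalogue$introns$species_id)
  n <- as.integer(counts[names(catalogue$records)])
  n[is.na(n)] <- 0L
  data.frame(
    species_id = names(catalogue$records),
    taxon_division = vapply(catalogue$records, `[[`, character(1),
                            "taxon_division"),
    n_introns = n,
    row.names = NULL)
}

#' Position distribution of introns
#'
#' Maps every position-resolved assignment onto its reference codon
#' position; positions carrying at least two introns are classified
#' `common`, positions with a single intron `unique`. Introns without a
#' resolved position (`NA` ref_codon) are excluded and counted separately.
#'
#' @param assignments assignments table from [assign_positions()].
#' @return list with `positions` (data frame: `ref_codon`, `n_introns`,
#'   `class`), `members` (data frame: `ref_codon`, `name`, `phase`,
#'   `intron_id`, sorted by name within position) and `n_unresolved`.
#' @export
position_distribution <- function(assignments) {
  ok <- !is.na(assignments$ref_codon)
  m <- assignments[ok, c("ref_codon", "name", "phase", "intron_id")]
  m <- m[order(m$ref_codon, m$name, m$intron_id), , drop = FALSE]
  rownames(m) <- NULL
  counts <- table(m$ref_codon)
  positions <- data.frame(
    ref_codon = as.integer(names(counts)),
    n_introns = as.integer(counts),
    class = ifelse(as.integer(counts) >= 2L, "common", "unique"))
  positions <- positions[order(positions$ref_codon), , drop = FALSE]
  rownames(positions) <- NULL
  list(positions = positions, members = m, n_unresolved = sum(!ok))
}

#' Report species constrained at the QoI resistance codon
#'
#' Species carrying an intron at the reference codon (by default 143, the
#' site of the G143A QoI-resistance substitution) cannot acquire the
#' resistance mutation without disrupting splicing; they are reported as
#' constrained, all others as unconstrained.
#'
#' @param assignments assignments table.
#' @param species all species ids of the catalogue (so intron-free genes
#'   are reported too); defaults to the species present in `assignments`.
#' @param codon constrained reference codon, default 143.
#' @return data frame: `species_id`, `constrained`, `introns` (names at
#'   the codon, comma-separated).
#' @export
qoi_constraint_report <- function(assignments, species = NULL,
                                  codon = 143L) {
  species <- sort(species %||% unique(assignments$species_id))
  at <- assignments[!is.na(assignments$ref_codon) &
                      assignments$ref_codon == codon, , drop = FALSE]
  rows <- lapply(species, function(sp) {
    nm <- sort(at$name[at$species_id == sp])
    data.frame(species_id = sp, constrained = length(nm) > 0L,
               introns = paste(nm, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
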