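# Codon/phase arithmetic, translation, reference-coordinate mapping via
# protein alignment, sliding-intron normalization and paper-style naming.

#' Codon position and phase of an insertion point
#'
#' The insertion point `p` counts coding nucleotides 5' of the intron. The
#' interrupted codon is `ceiling(p/3)`; the phase is 0 when the intron
#' falls between two codons, 1 after the first base of a codon, and 2
#' after the second — i.e. `p mod 3`. The inverse is
#' `p = 3 (codon - 1) + (3 if phase == 0 else phase)`.
#'
#' @param p insertion point(s), `p >= 1`.
#' @return data frame with columns `codon` and `phase`.
#' @export
#' @examples
#' codon_and_phase(201)   # codon 67, phase 0
#' codon_and_phase(490)   # codon 164, phase 1
codon_and_phase <- function(p) {
  stopifnot(all(p >= 1))
  data.frame(codon = as.integer(ceiling(p / 3)),
             phase = as.integer(p %% 3))
}

#' Insertion point from codon and phase
#' @param codon codon index. @param phase 0, 1 or 2.
#' @return integer insertion point.
#' @export
insertion_point <- function(codon, phase) {
  as.integer(3L * (codon - 1L) + ifelse(phase == 0L, 3L, phase))
}

#' Translate a coding sequence
#'
#' Uses NCBI translation table 4 (mold mitochondrial; TGA = Trp) by
#' default. The trailing stop is dropped; an internal stop raises an error
#' (it usually signals a wrong table or frame).
#'
#' @param cdna coding sequence, length a multiple of 3.
#' @param table NCBI genetic-code table id (character), default `"4"`.
#' @return protein string, one letter per codon.
#' @export
translate_coding <- function(cdna, table = "4") {
  if (nchar(cdna) %% 3L != 0L)
    cob_error("cdna length is not a multiple of 3",
              "cobintron_cdna_not_codon_multiple")
  code <- Biostrings::getGeneticCode(table)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cdna),
                                           genetic.code = code,
                                           if.fuzzy.codon = "solve"))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE))
    cob_error(sprintf("internal stop codon at residue %d (wrong table or frame?)",
                      regexpr("*", aa, fixed = TRUE)[1]),
              "cobintron_internal_stop")
  aa
}

#' Map a codon position onto reference coordinates
#'
#' Globally aligns the query protein to the reference protein (affine gaps,
#' BLOSUM62) and reports the reference codon aligned to the query codon.
#' When the query codon faces a reference gap, the nearest reference
#' residue to the left is reported and the result is flagged. The phase is
#' carried unchanged by the caller.
#'
#' @param native_codon codon index (or vector) in the query's own gene.
#' @param query_protein,reference_protein protein strings.
#' @return data frame with `ref_codon` and logical `ref_gap` flag.
#' @export
map_position_to_reference <- function(native_codon, query_protein,
                                      reference_protein) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_protein),
    Biostrings::AAString(reference_protein),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global")
  q <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  r <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  qi <- cumsum(q != "-")
  ri <- cumsum(r != "-")
  out <- lapply(native_codon, function(cod) {
    col <- which(qi == cod & q != "-")
    if (!length(col))
      cob_error(sprintf("query codon %d outside the alignment span", cod),
                "cobintron_outside_alignment")
    col <- col[1]
    if (r[col] != "-") data.frame(ref_codon = ri[col], ref_gap = FALSE)
    else data.frame(ref_codon = max(1L, ri[col]), ref_gap = TRUE)
  })
  do.call(rbind, out)
}

#' Assign reference positions, phases and names to all introns
#'
#' Runs the full position-mapping stage: codon/phase from each insertion
#' point, translation of every coding sequence (table 4), protein alignment
#' of each species against the reference species, sliding-intron
#' normalization, and paper-style naming. Introns whose position cannot be
#' determined can be injected later with `NA` positions; they are retained
#' but excluded from position-based analyses.
#'
#' @param catalogue catalogue with extracted introns.
#' @param reference species_id of the reference gene (its own introns
#'   self-map, so its assignments equal [codon_and_phase()] output).
#' @param table genetic-code table id.
#' @param normalize_sliding run [normalize_sliding_introns()]?
#' @param sliding_window_nt two introns closer than this many nucleotides
#'   (strictly) in reference coordinates are sliding candidates; default 6.
#' @return catalogue with an `assignments` data frame: `intron_id`,
#'   `species_id`, `native_codon`, `phase`, `ref_codon`, `ref_gap`,
#'   `slid_by`, `unresolved_sliding`, `name`.
#' @export
assign_positions <- function(catalogue, reference,
                             table = "4", normalize_sliding = TRUE,
                             sliding_window_nt = 6L) {
  if (!reference %in% names(catalogue$records))
    cob_error(sprintf("reference species '%s' not in catalogue", reference),
              "cobintron_bad_reference")
  intr <- catalogue$introns
  if (is.null(intr))
    cob_error("extract introns before assigning positions",
              "cobintron_no_introns")
  prots <- lapply(catalogue$records, function(r)
    translate_coding(r$cdna, table))
  ref_prot <- prots[[reference]]
  asn <- list()
  for (sp in names(catalogue$records)) {
    rows <- intr[intr$species_id == sp, , drop = FALSE]
    if (!nrow(rows)) next
    cp <- codon_and_phase(rows$insertion_point)
    mapped <- map_position_to_reference(cp$codon, prots[[sp]], ref_prot)
    asn[[sp]] <- data.frame(
      intron_id = rows$intron_id, species_id = sp,
      native_codon = cp$codon, phase = cp$phase,
      ref_codon = mapped$ref_codon, ref_gap = mapped$ref_gap,
      slid_by = 0L, unresolved_sliding = FALSE,
      name = NA_character_)
  }
  asn <- do.call(rbind, asn)
  rownames(asn) <- NULL
  out <- new_catalogue(catalogue$records, introns = intr,
                       assignments = asn, provenance = catalogue$provenance)
  if (normalize_sliding)
    out <- normalize_sliding_introns(out, window_nt = sliding_window_nt)
  assign_names(out)
}

# reference nucleotide-scale location of an assignment
ref_nt_location <- function(ref_codon, phase) {
  3L * (ref_codon - 1L) + ifelse(phase == 0L, 3L, phase)
}

#' Normalize sliding introns
#'
#' Introns from different genes whose reference locations differ by fewer
#' than `window_nt` nucleotides are sliding candidates. For each such
#' group, signed boundary shifts of at most 5 nt are sought that (a) keep
#' each gdna intact (bases merely move between exon and intron), (b) leave
#' every shifted intron ending in G with a preceding exonic T, and (c)
#' bring all locations of the group to one point. The feasible solution
#' with the smallest total |shift| is applied (ties toward the smaller
#' location); groups with no solution keep their locations and are flagged
#' `unresolved_sliding`. The operation is idempotent.
#'
#' @param catalogue catalogue with assignments.
#' @param window_nt strict sliding window in nucleotides (default 6).
#' @return catalogue with adjusted assignments (audit columns `slid_by`,
#'   `unresolved_sliding`).
#' @export
normalize_sliding_introns <- function(catalogue, window_nt = 6L) {
  asn <- catalogue$assignments
  intr <- catalogue$introns
  ok <- !is.na(asn$ref_codon)
  loc <- rep(NA_integer_, nrow(asn))
  loc[ok] <- ref_nt_location(asn$ref_codon[ok], asn$phase[ok])

  # single-linkage groups of near-coincident locations across genes
  idx <- which(ok)
  idx <- idx[order(loc[idx])]
  grp <- integer(0); groups <- list()
  for (i in idx) {
    if (length(grp) && loc[i] - loc[grp[length(grp)]] < window_nt)
      grp <- c(grp, i)
    else {
      if (length(grp) > 1L) groups[[length(groups) + 1L]] <- grp
      grp <- i
    }
  }
  if (length(grp) > 1L) groups[[length(groups) + 1L]] <- grp

  for (g in groups) {
    if (length(unique(asn$species_id[g])) < 2L) next
    if (length(unique(loc[g])) == 1L) next
    sol <- solve_sliding_group(loc[g], asn$intron_id[g], intr)
    if (is.null(sol)) {
      asn$unresolved_sliding[g] <- TRUE
    } else {
      for (j in seq_along(g)) {
        i <- g[j]; sh <- sol$shifts[j]
        if (sh == 0L) next
        row <- match(asn$intron_id[i], intr$intron_id)
        intr[row, ] <- shift_intron_row(intr[row, ], sh)
        newloc <- loc[i] + sh
        asn$ref_codon[i] <- as.integer(ceiling(newloc / 3))
        asn$phase[i] <- newloc %% 3L
        asn$native_codon[i] <-
          codon_and_phase(intr$insertion_point[row])$codon
        asn$slid_by[i] <- asn$slid_by[i] + sh
      }
    }
  }
  new_catalogue(catalogue$records, introns = intr, assignments = asn,
                provenance = catalogue$provenance)
}

# feasible shifts for one intron row: 0 always (keeps location); a nonzero
# shift needs the shifted boundary to satisfy the splice consensus
feasible_shifts <- function(row) {
  L <- nchar(row$sequence)
  up <- row$upstream_flank; dn <- row$downstream_flank
  sh <- 0L
  for (j in 1:5) {                               # slide right by j
    if (j <= nchar(dn) && j <= L) {
      term <- substr(dn, j, j)
      prec <- substr(row$sequence, j, j)
      if (term == "G" && prec == "T") sh <- c(sh, j)
    }
    if (j <= nchar(up) && j <= L) {              # slide left by j
      term <- substr(row$sequence, L - j, L - j)
      prec <- substr(up, nchar(up) - j, nchar(up) - j)
      if (j < L && nchar(up) > j && term == "G" && prec == "T")
        sh <- c(sh, -j)
    }
  }
  sh
}

solve_sliding_group <- function(locs, intron_ids, intr) {
  feas <- lapply(intron_ids, function(id)
    feasible_shifts(intr[match(id, intr$intron_id), ]))
  targets <- sort(unique(unlist(mapply(function(l, f) l + f, locs, feas,
                                       SIMPLIFY = FALSE))))
  best <- NULL
  for (tg in targets) {
    sh <- tg - locs
    okv <- mapply(function(s, f) s %in% f, sh, feas)
    if (all(okv)) {
      cost <- sum(abs(sh))
      if (is.null(best) || cost < best$cost) best <-
          list(target = tg, shifts = as.integer(sh), cost = cost)
    }
  }
  best
}

# apply a boundary slide of `sh` nt to one intron-table row (gdna is
# unchanged; the annotated exon/intron boundary moves)
shift_intron_row <- function(row, sh) {
  L <- nchar(row$sequence)
  up <- row$upstream_flank; dn <- row$downstream_flank
  if (sh > 0L) {
    new_seq <- paste0(substr(row$sequence, sh + 1L, L), substr(dn, 1L, sh))
    new_up <- paste0(substr(up, sh + 1L, nchar(up)),
                     substr(row$sequence, 1L, sh))
    new_dn <- substr(dn, sh + 1L, nchar(dn))
  } else {
    k <- -sh
    new_seq <- paste0(substr(up, nchar(up) - k + 1L, nchar(up)),
                      substr(row$sequence, 1L, L - k))
    new_dn <- paste0(substr(row$sequence, L - k + 1L, L),
                     substr(dn, 1L, nchar(dn)))
    new_up <- substr(up, 1L, nchar(up) - k)
  }
  row$sequence <- new_seq
  row$upstream_flank <- new_up
  row$downstream_flank <- substr(new_dn, 1L, 5L)
  row$insertion_point <- row$insertion_point + sh
  row$upstream_exon_base <- substr(new_up, nchar(new_up), nchar(new_up))
  row$terminal_base <- substr(new_seq, L, L)
  row
}

#' Assign paper-style intron names
#'
#' The abbreviation is the first letter of the genus plus the first letter
#' of the species epithet (from `species_name`; the `species_id` is used
#' verbatim when no binomial is available). Colliding abbreviations are
#' extended with the first epithet letter that distinguishes them (e.g.
#' fructicola/fructigena -> `Mfc`/`Mfg`). Introns are numbered 1..k in 5'
#' to 3' order; the number is omitted when a species has exactly one
#' intron.
#'
#' @param catalogue catalogue with assignments.
#' @return catalogue with the `name` column filled (a bijection between
#'   introns and names).
#' @export
assign_names <- function(catalogue) {
  asn <- catalogue$assignments
  intr <- catalogue$introns
  species <- sort(unique(intr$species_id))
  binom <- vapply(species, function(sp) {
    nm <- catalogue$records[[sp]]$species_name
    if (is.na(nm)) "" else nm
  }, character(1))
  abbr <- species_abbreviations(species, binom)
  for (sp in species) {
    rows <- which(intr$species_id == sp)
    ords <- intr$ordinal[rows]
    nm <- if (length(rows) == 1L) abbr[[sp]]
          else paste0(abbr[[sp]], ords)
    ai <- match(intr$intron_id[rows], asn$intron_id)
    asn$name[ai[!is.na(ai)]] <- nm[!is.na(ai)]
    intr$name <- intr$name %||% NA_character_
    intr$name[rows] <- nm
  }
  new_catalogue(catalogue$records, introns = intr, assignments = asn,
                provenance = catalogue$provenance)
}

species_abbreviations <- function(species, binom) {
  base <- vapply(seq_along(species), function(i) {
    parts <- strsplit(trimws(binom[i]), "\\s+")[[1]]
    if (length(parts) >= 2L)
      paste0(toupper(substr(parts[1], 1, 1)), tolower(substr(parts[2], 1, 1)))
    else species[i]
  }, character(1))
  epithet <- vapply(seq_along(species), function(i) {
    parts <- strsplit(trimws(binom[i]), "\\s+")[[1]]
    if (length(parts) >= 2L) tolower(parts[2]) else species[i]
  }, character(1))
  # extend colliding abbreviations by the first distinguishing epithet letter
  resolve <- function(ids, ab) {
    tab <- split(ids, ab[ids])
    for (grp in tab) {
      if (length(grp) < 2L) next
      eps <- epithet[grp]
      k <- 1L
      while (k <= min(nchar(eps)) &&
             length(unique(substr(eps, k, k))) == 1L) k <- k + 1L
      ab[grp] <- paste0(ab[grp], substr(eps, k, k))
      ab <- resolve(grp, ab)
    }
    ab
  }
  ab <- resolve(seq_along(species), base)
  setNames(ab, species)
}
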