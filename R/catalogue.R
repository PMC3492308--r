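# Gene records, the intron catalogue container, and its external
# representations (FASTA pairs, Newick trees, TSV tables).

#' Construct a gene record
#'
#' A gene record holds one species' cob gene: the genomic sequence of the
#' gene region (start codon through stop codon, introns included) and the
#' spliced coding sequence. Sequences are canonicalized to uppercase with U
#' mapped to T.
#'
#' @param species_id short unique label (used as FASTA key and tree leaf).
#' @param gdna genomic sequence of the gene region.
#' @param cdna spliced coding sequence, start codon through stop codon.
#' @param accession sequence database accession, or `NA`.
#' @param species_name binomial name (used for intron naming), or `NA`.
#' @param taxon_division taxonomic division, conventionally one of
#'   `"Fungi"`, `"Metazoa"`, `"Plants"`, `"Protista"`; free text allowed.
#' @return an object of class `gene_record`.
#' @export
#' @examples
#' gene_record("sp1", gdna = "ATGAAATAA", cdna = "ATGAAATAA")
gene_record <- function(species_id, gdna, cdna, accession = NA_character_,
                        species_name = NA_character_,
                        taxon_division = "Fungi") {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            nzchar(species_id))
  gdna <- canonical_seq(gdna, sprintf("gdna of '%s'", species_id))
  cdna <- canonical_seq(cdna, sprintf("cdna of '%s'", species_id))
  if (nchar(cdna) %% 3L != 0L)
    cob_error(sprintf("cdna of '%s' has length %d, not a multiple of 3",
                      species_id, nchar(cdna)),
              "cobintron_cdna_not_codon_multiple")
  if (nchar(cdna) > nchar(gdna))
    cob_error(sprintf("cdna of '%s' (%d nt) is longer than its gdna (%d nt)",
                      species_id, nchar(cdna), nchar(gdna)),
              "cobintron_cdna_longer_than_gdna")
  structure(list(species_id = species_id, accession = accession,
                 species_name = species_name,
                 taxon_division = taxon_division,
                 gdna = gdna, cdna = cdna),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s (%s): gdna %d nt, cdna %d nt [%s]\n",
              x$species_id,
              if (is.na(x$species_name)) "unnamed" else x$species_name,
              nchar(x$gdna), nchar(x$cdna), x$taxon_division))
  invisible(x)
}

#' Assemble an intron catalogue
#'
#' The catalogue is the pipeline's working container: gene records keyed by
#' species, the intron table, optional position assignments, and free-form
#' provenance. Records are canonically sorted by `species_id` and introns by
#' species then insertion point, so downstream results are independent of
#' input order.
#'
#' @param records list of [gene_record()] objects.
#' @param introns intron table as returned by [extract_introns()] (rows may
#'   cover several species); may be `NULL` before extraction.
#' @param assignments position-assignment table from [assign_positions()];
#'   may be `NULL`.
#' @param provenance named list of free-text provenance.
#' @return an object of class `cob_catalogue`.
#' @export
new_catalogue <- function(records, introns = NULL, assignments = NULL,
                          provenance = list()) {
  ids <- vapply(records, function(r) r$species_id, character(1))
  if (anyDuplicated(ids))
    cob_error("duplicated species_id in records", "cobintron_dup_species")
  records <- records[order(ids)]
  names(records) <- sort(ids)
  if (!is.null(introns) && nrow(introns)) {
    orphan <- setdiff(unique(introns$species_id), names(records))
    if (length(orphan))
      cob_error(sprintf("introns reference unknown species: %s",
                        paste(orphan, collapse = ", ")),
                "cobintron_orphan_intron")
    introns <- introns[order(introns$species_id, introns$insertion_point), ,
                       drop = FALSE]
    rownames(introns) <- NULL
    if (anyDuplicated(introns$intron_id))
      cob_error("duplicated intron_id in catalogue", "cobintron_dup_intron")
    if (!is.null(introns$name) &&
        anyDuplicated(stats::na.omit(introns$name)))
      cob_error("duplicated intron name in catalogue", "cobintron_dup_name")
  }
  structure(list(records = records, introns = introns,
                 assignments = assignments, provenance = provenance),
            class = "cob_catalogue")
}

#' @export
print.cob_catalogue <- function(x, ...) {
  cat(sprintf("<cob_catalogue> %d gene records, %d introns, %s\n",
              length(x$records),
              if (is.null(x$introns)) 0L else nrow(x$introns),
              if (is.null(x$assignments)) "positions unassigned"
              else "positions assigned"))
  invisible(x)
}

## ---- FASTA pair convention -------------------------------------------

#' Read gene records
#'
#' Two input dialects are supported. `"fasta-pair"` expects every species to
#' contribute two FASTA entries named `<id>|gdna` and `<id>|cdna`. Header
#' text after the first whitespace is kept as the species name; an
#' `acc=<accession>` token and a `division=<division>` token are honoured.
#' `"genbank"` reads GenBank flat files carrying an annotated cob CDS whose
#' exon coordinates splice the cdna out of the genomic sequence (see
#' [read_genbank_gene()]).
#'
#' @param paths files to read (FASTA files, or one GenBank flat file per
#'   record).
#' @param format `"fasta-pair"` or `"genbank"`.
#' @return list of [gene_record()] objects, sorted by species id.
#' @export
read_gene_records <- function(paths, format = c("fasta-pair", "genbank")) {
  format <- match.arg(format)
  if (format == "genbank") {
    recs <- lapply(paths, read_genbank_gene)
  } else {
    entries <- list()
    for (p in paths) entries <- c(entries, read_fasta_entries(p))
    headers <- vapply(entries, `[[`, character(1), "header")
    keys <- sub("\\s.*$", "", headers)
    parts <- strsplit(keys, "|", fixed = TRUE)
    ok <- lengths(parts) == 2L & vapply(parts, function(x)
      x[2] %in% c("gdna", "cdna"), logical(1))
    if (!all(ok))
      cob_error(sprintf("FASTA headers must be '<id>|gdna' or '<id>|cdna'; offending: %s",
                        paste(keys[!ok], collapse = ", ")),
                "cobintron_bad_fasta_key")
    ids <- vapply(parts, `[[`, character(1), 1L)
    role <- vapply(parts, `[[`, character(1), 2L)
    recs <- lapply(sort(unique(ids)), function(id) {
      gi <- which(ids == id & role == "gdna")
      ci <- which(ids == id & role == "cdna")
      if (length(gi) != 1L || length(ci) != 1L)
        cob_error(sprintf("species '%s' must have exactly one gdna and one cdna entry",
                          id),
                  "cobintron_missing_mate")
      meta <- parse_fasta_meta(headers[gi])
      gene_record(id, gdna = entries[[gi]]$seq, cdna = entries[[ci]]$seq,
                  accession = meta$accession, species_name = meta$species_name,
                  taxon_division = meta$division)
    })
  }
  recs[order(vapply(recs, `[[`, character(1), "species_id"))]
}

# ">id|gdna Genus species acc=XX division=Fungi" -> metadata fields
parse_fasta_meta <- function(header) {
  rest <- sub("^\\S+\\s*", "", header)
  toks <- strsplit(trimws(rest), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  acc <- sub("^acc=", "", grep("^acc=", toks, value = TRUE))
  div <- sub("^division=", "", grep("^division=", toks, value = TRUE))
  name <- toks[!grepl("=", toks, fixed = TRUE)]
  list(accession = if (length(acc)) acc[1] else NA_character_,
       species_name = if (length(name)) paste(name, collapse = " ")
                      else NA_character_,
       division = if (length(div)) div[1] else "Fungi")
}

read_fasta_entries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts))
    cob_error(sprintf("no FASTA entries in %s", path), "cobintron_bad_fasta")
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    list(header = sub("^>", "", lines[starts[i]]),
         seq = paste(lines[(starts[i] + 1L):ends[i]], collapse = ""))
  })
}

#' Write gene records as paired FASTA
#'
#' Inverse of [read_gene_records()] for the `"fasta-pair"` dialect; each
#' record contributes a `<id>|gdna` and a `<id>|cdna` entry with species
#' name, `acc=` and `division=` tokens in the header.
#'
#' @param records list of [gene_record()].
#' @param path output FASTA file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in records[order(vapply(records, `[[`, character(1), "species_id"))]) {
    meta <- paste0(if (!is.na(r$species_name)) paste0(" ", r$species_name) else "",
                   if (!is.na(r$accession)) paste0(" acc=", r$accession) else "",
                   " division=", r$taxon_division)
    for (role in c("gdna", "cdna")) {
      writeLines(sprintf(">%s|%s%s", r$species_id, role, meta), con)
      writeLines(wrap_seq(r[[role]], width), con)
    }
  }
  invisible(path)
}

wrap_seq <- function(x, width = 70L) {
  n <- nchar(x)
  substring(x, seq(1L, n, width), pmin(seq(1L, n, width) + width - 1L, n))
}

## ---- species tree ----------------------------------------------------

#' Read a species tree
#'
#' Parses a Newick file into an `ape::phylo` tree. The tree is rooted (as
#' written); polytomies and missing branch lengths are allowed. When a
#' catalogue is supplied, leaves absent from it are reported as a warning,
#' not an error, and attached as the `"unmatched_leaves"` attribute.
#'
#' @param path Newick file.
#' @param catalogue optional [new_catalogue()] to check leaf labels against.
#' @return a rooted `phylo` object.
#' @export
read_species_tree <- function(path, catalogue = NULL) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) NULL)
  if (is.null(tree))
    cob_error(sprintf("could not parse Newick in %s", path),
              "cobintron_bad_newick")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (!is.null(catalogue)) {
    missing <- setdiff(tree$tip.label, names(catalogue$records))
    if (length(missing))
      cob_warn(sprintf("tree leaves not in catalogue: %s",
                       paste(missing, collapse = ", ")),
               "cobintron_unmatched_leaves")
    attr(tree, "unmatched_leaves") <- missing
  }
  tree
}

## ---- TSV tables ------------------------------------------------------

#' Write catalogue tables
#'
#' Writes the intron table (one row per intron: name, species, accession,
#' reference position, phase, length, insertion point) and the
#' position-distribution table (one column per occupied reference codon
#' position, member introns rendered `Name(phase)`, and per-position counts
#' as the final row). All coordinates are 1-based and inclusive; insertion
#' points count coding nucleotides 5' of the intron.
#'
#' @param catalogue catalogue with computed assignments.
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_catalogue_tables <- function(catalogue, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(out_dir, "introns.tsv")
  f2 <- file.path(out_dir, "position_distribution.tsv")
  asn <- catalogue$assignments
  intr <- catalogue$introns
  if (is.null(intr) || !nrow(intr)) {
    writeLines(paste(c("name", "species_id", "accession", "ref_codon",
                       "phase", "length", "insertion_point"),
                     collapse = "\t"), f1)
    writeLines("position", f2)
    return(invisible(c(f1, f2)))
  }
  acc <- vapply(catalogue$records, `[[`, character(1), "accession")
  tab <- merge(intr[, setdiff(names(intr), c("name", "phase"))],
               asn[, c("intron_id", "ref_codon", "phase", "name")],
               by = "intron_id")
  tab$accession <- acc[tab$species_id]
  tab <- tab[order(tab$species_id, tab$insertion_point),
             c("name", "species_id", "accession", "ref_codon", "phase",
               "length", "insertion_point")]
  write.table(tab, f1, sep = "\t", quote = FALSE, row.names = FALSE)

  dist <- position_distribution(asn)
  cells <- lapply(dist$positions$ref_codon, function(p) {
    m <- dist$members[dist$members$ref_codon == p, ]
    sprintf("%s(%d)", m$name, m$phase)
  })
  depth <- max(c(1L, lengths(cells)))
  mat <- vapply(cells, function(x) c(x, rep("", depth - length(x))),
                character(depth))
  mat <- rbind(matrix(mat, nrow = depth),
               as.character(dist$positions$n_introns))
  colnames(mat) <- as.character(dist$positions$ref_codon)
  write.table(mat, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
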