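# Minimal GenBank flat-file reader for single-gene records. Only what the
# catalogue needs is parsed: accession, organism, taxonomy, the cob CDS
# feature's exon coordinates, and the ORIGIN sequence. None of the installed
# R packages parses *local* GenBank flat files (ape::read.GenBank and
# seqinr's interfaces fetch from the network), hence this small parser.

#' Read one GenBank flat file into a gene record
#'
#' Locates a CDS feature for cytochrome b (`/gene` of `cob`, `COB` or
#' `cytb`, or a `/product` mentioning "cytochrome b"; if no such feature is
#' annotated, the first CDS is used). The gene region is the span from the
#' first to the last exon coordinate, and the cdna is spliced from the exon
#' segments of a `join(...)` location; `complement(...)` locations are
#' reverse-complemented onto the coding strand. A CDS with a single segment
#' yields an intronless record.
#'
#' @param path GenBank flat file.
#' @param species_id optional label; defaults to the accession.
#' @return a [gene_record()].
#' @export
read_genbank_gene <- function(path, species_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
             grep("^ACCESSION", lines, value = TRUE)[1])
  org <- sub("^\\s*ORGANISM\\s+", "",
             grep("^\\s*ORGANISM", lines, value = TRUE)[1])
  if (is.na(acc)) acc <- NA_character_
  division <- genbank_division(lines)

  ori <- grep("^ORIGIN", lines)
  if (!length(ori))
    cob_error(sprintf("%s: no ORIGIN block", path), "cobintron_bad_genbank")
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  full <- canonical_seq(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")),
                        sprintf("sequence of %s", path))

  loc <- genbank_cds_location(lines, ori[1], path)
  segs <- loc$segments
  span <- c(min(segs[, 1]), max(segs[, 2]))
  gdna <- substr(full, span[1], span[2])
  exons <- apply(segs, 1L, function(s) substr(full, s[1], s[2]))
  cdna <- paste(exons, collapse = "")
  if (loc$complement) {
    gdna <- revcomp(gdna)
    cdna <- revcomp(cdna)
  }
  gene_record(species_id %||% acc, gdna = gdna, cdna = cdna,
              accession = acc, species_name = org,
              taxon_division = division)
}

genbank_division <- function(lines) {
  tax <- paste(lines[grepl("^\\s{8,}", lines) &
                       cumsum(grepl("^\\s*ORGANISM", lines)) > 0 &
                       cumsum(grepl("^REFERENCE|^FEATURES", lines)) == 0],
               collapse = " ")
  if (grepl("Fungi", tax)) "Fungi"
  else if (grepl("Metazoa", tax)) "Metazoa"
  else if (grepl("Viridiplantae|Streptophyta|Chlorophyta", tax)) "Plants"
  else if (nzchar(tax)) "Protista"
  else "Fungi"
}

# Extract the cob CDS location string, preferring cob/cytb-labelled CDS.
genbank_cds_location <- function(lines, origin_at, path) {
  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start))
    cob_error(sprintf("%s: no FEATURES block", path), "cobintron_bad_genbank")
  flines <- lines[(feat_start[1] + 1L):(origin_at - 1L)]
  is_new <- grepl("^\\s{5}\\S", flines)
  idx <- which(is_new)
  feats <- lapply(seq_along(idx), function(i) {
    from <- idx[i]
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(flines)
    block <- flines[from:to]
    key <- sub("^\\s+(\\S+).*$", "\\1", block[1])
    list(key = key, text = paste(trimws(block), collapse = " "))
  })
  cds <- feats[vapply(feats, function(f) f$key == "CDS", logical(1))]
  if (!length(cds))
    cob_error(sprintf("%s: no CDS feature", path), "cobintron_no_cds")
  is_cob <- vapply(cds, function(f)
    grepl("/gene=\"(cob|COB|cytb|CYTB|Cytb)\"", f$text) ||
      grepl("/product=\"[^\"]*[Cc]ytochrome b", f$text), logical(1))
  f <- if (any(is_cob)) cds[[which(is_cob)[1]]] else cds[[1]]
  locstr <- sub("^CDS\\s+", "", f$text)
  locstr <- sub("\\s*/.*$", "", locstr)       # drop qualifiers
  locstr <- gsub("\\s", "", locstr)
  parse_genbank_location(locstr, path)
}

parse_genbank_location <- function(locstr, path = "<location>") {
  complement <- FALSE
  x <- locstr
  if (grepl("^complement\\(", x)) {
    complement <- TRUE
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) x <- sub("^join\\((.*)\\)$", "\\1", x)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$|^(\\d+)$", parts))
  segs <- t(vapply(m, function(g) {
    if (!length(g) || !nzchar(g[1]))
      cob_error(sprintf("%s: unsupported CDS location '%s'", path, locstr),
                "cobintron_bad_genbank")
    if (nzchar(g[4])) rep(as.integer(g[4]), 2L)
    else c(as.integer(g[2]), as.integer(g[3]))
  }, integer(2)))
  list(segments = segs, complement = complement)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
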