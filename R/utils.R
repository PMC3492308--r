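# Internal sequence and error helpers. Sequences are plain uppercase
# character strings throughout; Biostrings objects are built only at the
# alignment/translation boundary.

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_LETTERS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

cob_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cobintron_error", "error")))
}

cob_warn <- function(msg, class = "cobintron_warning") {
  warning(warningCondition(msg, class = c(class, "warning")))
}

#' Canonicalize a nucleotide sequence
#'
#' Uppercases, maps U to T and validates against the IUPAC alphabet.
#'
#' @param x character scalar.
#' @param what label used in error messages.
#' @return canonical sequence string.
#' @keywords internal
canonical_seq <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    cob_error(sprintf("%s must be a non-empty string", what),
              "cobintron_bad_sequence")
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  letters <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  bad <- setdiff(letters, IUPAC_LETTERS)
  if (length(bad))
    cob_error(sprintf("%s contains non-IUPAC letters: %s", what,
                      paste(bad, collapse = ", ")),
              "cobintron_bad_sequence")
  x
}

# substring by integer positions (1-based inclusive)
subseq_chr <- function(x, from, to) substr(x, from, to)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# length of the common prefix of a[ia..] and b[ib..], on raw vectors
lcp_len <- function(ra, ia, rb, ib) {
  n <- min(length(ra) - ia + 1L, length(rb) - ib + 1L)
  if (n <= 0L) return(0L)
  eq <- ra[ia:(ia + n - 1L)] == rb[ib:(ib + n - 1L)]
  bad <- which(!eq)
  if (length(bad)) bad[1L] - 1L else n
}

# all start positions of fixed pattern in subject (1-based)
find_all <- function(pattern, subject, from = 1L) {
  if (from > nchar(subject)) return(integer(0))
  hits <- gregexpr(pattern, substr(subject, from, nchar(subject)),
                   fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) + from - 1L
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Percent identity between two equal-length sequences
#' @keywords internal
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ra <- charToRaw(a); rb <- charToRaw(b)
  100 * sum(ra == rb) / length(ra)
}

# round half away from zero (matches the printed-table convention)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
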