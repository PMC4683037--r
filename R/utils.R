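## Shared low-level helpers: alphabet handling, reverse complement,
## half-up rounding, Hamming distances. All sequence comparisons in the
## package run on the DNA alphabet; U is normalized to T on input.

#' Normalize a nucleotide string to the DNA alphabet
#'
#' U is replaced by T (case-insensitive input, upper-case output). All
#' comparisons inside the package treat T and U as equivalent; output
#' writers restore the original alphabet where it was recorded.
#'
#' @param x character vector of nucleotide strings.
#' @return upper-case character vector over A,C,G,T,N.
#' @export
normalize_nt <- function(x) {
  chartr("acgtunU", "ACGTTNT", toupper(x))
}

.valid_nt <- function(x) {
  !grepl("[^ACGTN]", normalize_nt(x))
}

#' Reverse complement
#'
#' @param x character vector of DNA strings (T alphabet; N maps to N).
#' @return reverse complements, same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", normalize_nt(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Round half away from zero
#'
#' Classification summaries report percentages rounded half-up to a fixed
#' number of decimals (R's \code{round} rounds half to even, which does not
#' match that reporting convention).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Hamming distance between one string and a vector of equal-length strings.
## Positions with N count as mismatches.
hamming_dist <- function(query, subjects) {
  n <- nchar(query)
  stopifnot(all(nchar(subjects) == n))
  q <- utf8ToInt(query)
  vapply(subjects, function(s) {
    v <- utf8ToInt(s)
    sum(v != q | v == utf8ToInt("N") | q == utf8ToInt("N"))
  }, integer(1), USE.NAMES = FALSE)
}

## GC percentage of a DNA string (0..100).
gc_percent <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  100 * gc / n
}

## Draw a random DNA string with a target GC fraction.
random_seq <- function(n, gc = 0.45) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## Vectorized substring extraction from a single long string.
## start is 0-based, width in nt; returns character vector.
substr_many <- function(seqstr, start0, width) {
  substring(seqstr, start0 + 1, start0 + width)
}
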