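#' @importFrom methods is
#' @importFrom stats median rgeom runif setNames cor
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Sample a random DNA string
#'
#' Uniform over A/C/G/T, using the current RNG state.
#'
#' @param n Length of the string in nucleotides.
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## sample() with a hole: length-1 x must not trigger 1:x expansion
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

is_probability <- function(p) {
  is.numeric(p) && length(p) == 1L && !is.na(p) && p >= 0 && p <= 1
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Set the RNG seed if one is given
#' @param seed Integer seed or `NULL` to leave the RNG state untouched.
#' @keywords internal
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
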