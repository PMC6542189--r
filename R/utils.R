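DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Reverse-complement of short character vectors (labels, half-sites).
## Long sequences go through Biostrings::reverseComplement instead.
revcompChar <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complementBase <- function(b) unname(DNA_COMPLEMENT[b])

## Bitmask over 1-based primary positions (n <= 30).
positionMask <- function(pos) {
  if (length(pos) == 0L) return(0L)
  as.integer(sum(bitwShiftL(1L, as.integer(pos) - 1L)))
}

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up, the convention used for the
#' printed two-decimal Poisson significance thresholds. `base::round()`
#' rounds half to even, which gives 0.125 -> 0.12 instead of 0.13.
#'
#' @param x numeric vector (non-negative values expected).
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Deterministic split of a user seed into stage seeds (kept < 2^31).
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483563)
}
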