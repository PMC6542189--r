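#' ElementSchema: a consensus palindromic response element
#'
#' An `ElementSchema` describes a palindromic cis-regulatory DNA element as
#' a half-site sequence plus a fixed-length unconstrained spacer. The full
#' consensus is `half_site + spacer + reverseComplement(half_site)`, so the
#' `n = 2 * nchar(half_site)` primary positions form a perfect inverted
#' repeat: the base at primary position `p` is the complement of the base at
#' position `n + 1 - p`. Positions `p` and `n + 1 - p` are called a
#' palindromic position pair; the spacer carries no sequence information and
#' is never numbered.
#'
#' @slot name label for the schema (e.g. `"ERE13"`).
#' @slot halfSite character; half-site sequence over A/C/G/T.
#' @slot spacerLen integer; spacer length in nucleotides (>= 0).
#'
#' @seealso [builtinSchema()] for the stock nuclear-receptor and p53 schemas.
#' @export
setClass("ElementSchema",
  representation(name = "character", halfSite = "character",
                 spacerLen = "integer"))

setValidity("ElementSchema", function(object) {
  msg <- character(0)
  if (length(object@halfSite) != 1L || nchar(object@halfSite) < 1L)
    msg <- c(msg, "halfSite must be a single non-empty string")
  else if (!all(strsplit(object@halfSite, "")[[1]] %in% DNA_BASES))
    msg <- c(msg, "halfSite must contain only A, C, G, T")
  if (length(object@spacerLen) != 1L || is.na(object@spacerLen) ||
      object@spacerLen < 0L)
    msg <- c(msg, "spacerLen must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct an ElementSchema
#'
#' @param name schema label.
#' @param halfSite half-site sequence (A/C/G/T), one string.
#' @param spacerLen spacer length in nucleotides.
#' @return An [ElementSchema-class] object.
#' @examples
#' ere <- ElementSchema("ERE13", "GGTCA", 3)
#' consensusSequence(ere)  # "GGTCANNNTGACC"
#' @export
ElementSchema <- function(name, halfSite, spacerLen = 0) {
  new("ElementSchema", name = as.character(name),
      halfSite = toupper(as.character(halfSite)),
      spacerLen = as.integer(spacerLen))
}

#' StateGrouping: a weighted partition of the palindromic pairs
#'
#' A `StateGrouping` partitions the `n/2` palindromic position pairs of a
#' schema into labelled classes and attaches one weight per class. The
#' *state* of a half-site group under a grouping is the sum of the class
#' weights of its vacancy pairs minus the sum of the class weights of its
#' double-occupant pairs; because every group has as many vacancies as
#' double occupants, only weight differences matter and the largest class
#' conventionally carries weight 0 (the reference).
#'
#' @slot schema the [ElementSchema-class] the grouping refers to.
#' @slot classes integer vector, one class index per palindromic pair
#'   (pairs ordered by their lower member `p = 1..n/2`).
#' @slot weights numeric vector, one weight per class.
#' @slot labels character vector of class labels (`"A"`, `"B"`, ...).
#' @export
setClass("StateGrouping",
  representation(schema = "ElementSchema", classes = "integer",
                 weights = "numeric", labels = "character"))

setValidity("StateGrouping", function(object) {
  h <- nPrimary(object@schema) %/% 2L
  nc <- max(object@classes)
  msg <- character(0)
  if (length(object@classes) != h)
    msg <- c(msg, sprintf("classes must assign each of the %d pairs", h))
  if (!all(object@classes %in% seq_len(nc)))
    msg <- c(msg, "class indices must be 1..nClasses with no gaps")
  if (length(object@weights) != nc)
    msg <- c(msg, "need exactly one weight per class")
  if (length(object@labels) != nc)
    msg <- c(msg, "need exactly one label per class")
  if (length(msg)) msg else TRUE
})

#' OccupancyModel: probabilistic occupancy of element variants
#'
#' Parameters of the synthetic cistrome generator's occupancy link. The
#' probability that an element occurrence is covered by a signal peak is
#' `plogis(alpha - beta * k + sum(pairWeights over substituted pairs) -
#' gamma * crossover)`, where `k` is the number of substitutions and
#' `crossover` indicates substitutions on both sides of the spacer. The
#' link depends only on which pairs are hit and whether the substitutions
#' cross the spacer, so it is invariant under reverse-complementing the
#' element: simulated occupancy is inversion-symmetric by construction.
#'
#' @slot alpha baseline log-odds of occupancy at the consensus.
#' @slot beta per-substitution log-odds decay (>= 0 for decaying signal).
#' @slot pairWeights named numeric, log-odds bonus per palindromic pair
#'   (names are pair labels such as `"3-8"`), applied once per pair that
#'   carries at least one substitution.
#' @slot gamma log-odds penalty when substitutions cross the spacer.
#' @export
setClass("OccupancyModel",
  representation(alpha = "numeric", beta = "numeric",
                 pairWeights = "numeric", gamma = "numeric"))

setValidity("OccupancyModel", function(object) {
  msg <- character(0)
  if (length(object@alpha) != 1L) msg <- c(msg, "alpha must be scalar")
  if (length(object@beta) != 1L) msg <- c(msg, "beta must be scalar")
  if (length(object@gamma) != 1L) msg <- c(msg, "gamma must be scalar")
  if (length(object@pairWeights) &&
      (is.null(names(object@pairWeights)) || anyNA(object@pairWeights)))
    msg <- c(msg, "pairWeights must be a named numeric vector")
  if (length(msg)) msg else TRUE
})

#' Construct an OccupancyModel
#'
#' @param alpha,beta,gamma scalar link parameters (see
#'   [OccupancyModel-class]).
#' @param pairWeights named numeric vector of per-pair weights; names must
#'   be the pair labels of the schema the model will be used with.
#' @return An [OccupancyModel-class] object.
#' @export
OccupancyModel <- function(alpha = 0, beta = 0.5, pairWeights = numeric(0),
                           gamma = 0) {
  new("OccupancyModel", alpha = as.numeric(alpha), beta = as.numeric(beta),
      pairWeights = pairWeights, gamma = as.numeric(gamma))
}

#' KmerCountTable: forward-strand k-mer counts
#'
#' Counts of every observed k-mer on the forward strand of one or more
#' sequences. Only observed k-mers are stored, so memory scales with the
#' distinct k-mers present, never with `4^k`; windows containing non-ACGT
#' characters (assembly gaps, sentinel breaks) are not counted and windows
#' never span record boundaries.
#'
#' @slot k word length.
#' @slot counts named integer vector of counts for observed k-mers.
#' @slot nWindows total number of valid windows counted.
#' @export
setClass("KmerCountTable",
  representation(k = "integer", counts = "integer", nWindows = "numeric"))

setValidity("KmerCountTable", function(object) {
  msg <- character(0)
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (length(object@counts) && is.null(names(object@counts)))
    msg <- c(msg, "counts must be named by k-mer")
  if (length(object@counts) && sum(as.numeric(object@counts)) !=
      object@nWindows)
    msg <- c(msg, "counts must sum to nWindows")
  if (length(msg)) msg else TRUE
})

#' @describeIn ElementSchema-class compact display.
#' @param object an `ElementSchema`.
#' @export
setMethod("show", "ElementSchema", function(object) {
  cat(sprintf("ElementSchema %s: 5'-%s-3' (n = %d primary positions, %d-nt spacer)\n",
              object@name, consensusSequence(object, spacer = "n"),
              nPrimary(object), object@spacerLen))
  cat("  palindromic pairs:", paste(pairLabels(object), collapse = ", "), "\n")
})

#' @describeIn StateGrouping-class compact display.
#' @param object a `StateGrouping`.
#' @export
setMethod("show", "StateGrouping", function(object) {
  sig <- paste(groupingSignature(object), collapse = ",")
  cat(sprintf("StateGrouping on %s: signature (%s)\n",
              object@schema@name, sig))
  pl <- pairLabels(object@schema)
  for (cl in seq_along(object@labels)) {
    cat(sprintf("  class %s (weight %g): %s\n", object@labels[cl],
                object@weights[cl],
                paste(pl[object@classes == cl], collapse = ", ")))
  }
})

#' @describeIn KmerCountTable-class compact display.
#' @param object a `KmerCountTable`.
#' @export
setMethod("show", "KmerCountTable", function(object) {
  cat(sprintf("KmerCountTable: k = %d, %d distinct k-mers, %.0f windows\n",
              object@k, length(object@counts), object@nWindows))
})

#' @describeIn OccupancyModel-class compact display.
#' @param object an `OccupancyModel`.
#' @export
setMethod("show", "OccupancyModel", function(object) {
  cat(sprintf("OccupancyModel: alpha = %g, beta = %g, gamma = %g\n",
              object@alpha, object@beta, object@gamma))
  if (length(object@pairWeights))
    cat("  pair weights:",
        paste(sprintf("%s=%g", names(object@pairWeights),
                      object@pairWeights), collapse = ", "), "\n")
})
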