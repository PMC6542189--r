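#' Construct a StateGrouping
#'
#' @param schema an [ElementSchema-class].
#' @param classes either an integer vector with one class index per
#'   palindromic pair (pairs in lower-member order), or a named list of
#'   pair-label vectors, one entry per class (pairs not listed fall into an
#'   implicit final reference class).
#' @param weights numeric weights, one per class; defaults to generic
#'   distinct weights with the last (reference) class at 0.
#' @param labels class labels; defaults to `"A"`, `"B"`, ...
#' @return A [StateGrouping-class].
#' @examples
#' ereStateGrouping(builtinSchema("ERE13"))
#' @export
StateGrouping <- function(schema, classes, weights = NULL, labels = NULL) {
  pl <- pairLabels(schema)
  h <- length(pl)
  if (is.list(classes)) {
    cl <- rep(length(classes) + 1L, h)
    for (i in seq_along(classes)) {
      j <- match(classes[[i]], pl)
      if (anyNA(j)) stop("unknown pair label in class ", i)
      cl[j] <- i
    }
    if (!any(cl == length(classes) + 1L)) cl <- cl  # all pairs listed
    classes <- as.integer(cl)
    ## drop the implicit reference class if empty
    classes <- match(classes, sort(unique(classes)))
  } else {
    classes <- as.integer(classes)
  }
  nc <- max(classes)
  if (is.null(weights)) weights <- c(seq_len(nc - 1L), 0)[seq_len(nc)]
  if (is.null(labels)) labels <- LETTERS[seq_len(nc)]
  new("StateGrouping", schema = schema, classes = classes,
      weights = as.numeric(weights), labels = as.character(labels))
}

#' @rdname StateGrouping
#' @details `ereStateGrouping()` is the (3,2,0,0,0) estrogen-receptor
#'   grouping: pairs 3-8 and 1-10 form class A with weight `X`, the other
#'   three pairs the reference class B with weight 0. It yields the
#'   five-state ladder `-2X, -X, 0, +X, +2X`. `hreStateGrouping()` is the
#'   (4,1,0,0,0) ketosteroid grouping: pair 2-9 alone in class A, giving
#'   the three-state ladder `-X, 0, +X`.
#' @param X numeric weight of the distinguished class.
#' @export
ereStateGrouping <- function(schema = builtinSchema("ERE13"), X = 1) {
  StateGrouping(schema, list(A = c("3-8", "1-10")), weights = c(X, 0))
}

#' @rdname StateGrouping
#' @export
hreStateGrouping <- function(schema = builtinSchema("HRE13"), X = 1) {
  StateGrouping(schema, list(A = "2-9"), weights = c(X, 0))
}

#' @rdname StateGrouping
#' @details `signatureGrouping()` builds a grouping from a partition
#'   signature such as `c(3, 2)` or `c(1, 1, 1, 1, 1)` (trailing zeros
#'   allowed): class sizes are assigned to the pairs in lower-member order.
#'   Which pairs land in which class does not affect state *counts*, only
#'   their biological interpretation.
#' @param signature integer vector of class sizes summing to `n/2`.
#' @export
signatureGrouping <- function(schema, signature) {
  signature <- as.integer(signature[signature > 0])
  h <- nPrimary(schema) %/% 2L
  if (sum(signature) != h)
    stop("class sizes must sum to the number of palindromic pairs (", h, ")")
  StateGrouping(schema, rep(seq_along(signature), signature))
}

#' @rdname StateGrouping
#' @param x a `StateGrouping`.
#' @export
setGeneric("groupingSignature", function(x) standardGeneric("groupingSignature"))

#' @describeIn StateGrouping the class-size signature, padded with zeros to
#'   `n/2` entries and sorted decreasingly.
#' @export
setMethod("groupingSignature", "StateGrouping", function(x) {
  h <- nPrimary(x@schema) %/% 2L
  sizes <- sort(tabulate(x@classes), decreasing = TRUE)
  c(sizes, rep(0L, h - length(sizes)))
})

## Per-group class coefficients: for each class c, (#vacancy pairs in c) -
## (#double-occupant pairs in c). The state is the weighted sum of these.
## Because |V| = |D| the coefficients always sum to zero, so states under
## generic weights are distinct exactly when the coefficient vectors are.
groupStateCoefficients <- function(groups, grouping) {
  pl <- pairLabels(grouping@schema)
  nc <- length(grouping@weights)
  coef <- matrix(0L, nrow(groups), nc,
                 dimnames = list(NULL, grouping@labels))
  tallies <- function(pairStr) {
    lapply(strsplit(pairStr, ","), function(p) {
      tabulate(grouping@classes[match(p[p != ""], pl)], nbins = nc)
    })
  }
  v <- tallies(groups$vacPairs)
  d <- tallies(groups$dblPairs)
  for (i in seq_len(nrow(groups))) coef[i, ] <- v[[i]] - d[[i]]
  coef
}

#' State of half-site groups under a grouping
#'
#' The state of a group is the sum of the class weights of its vacancy
#' pairs minus the sum of the class weights of its double-occupant pairs.
#' Reverse-complementing a group swaps vacancies and double occupants and
#' therefore negates the state.
#'
#' @param groups output of [enumerateHalfSiteGroups()] (any subset of rows).
#' @param grouping a [StateGrouping-class].
#' @return data.frame with the group `id`, one coefficient column per
#'   class (`coef.A`, ...), the numeric `state` under the grouping's
#'   weights, and a symbolic `stateLabel` built from the non-reference
#'   class symbols `X, Y, Z, ...` (classes in label order, reference = the
#'   zero-weight or last class).
#' @export
stateOfGroup <- function(groups, grouping) {
  coef <- groupStateCoefficients(groups, grouping)
  state <- drop(coef %*% grouping@weights)
  nc <- ncol(coef)
  ## symbolic label over non-reference classes
  ref <- if (any(grouping@weights == 0)) which(grouping@weights == 0)[1] else nc
  syms <- rep(NA_character_, nc)
  syms[setdiff(seq_len(nc), ref)] <- c("X", "Y", "Z", "W", "V")[
    seq_len(nc - 1L)]
  lab <- apply(coef, 1, function(cc) {
    parts <- character(0)
    for (j in setdiff(seq_len(nc), ref)) {
      if (cc[j] == 0) next
      mag <- if (abs(cc[j]) == 1L) syms[j] else paste0(abs(cc[j]), syms[j])
      parts <- c(parts, paste0(if (cc[j] > 0) "+" else "-", mag))
    }
    if (length(parts) == 0L) "0" else paste(parts, collapse = "")
  })
  out <- data.frame(id = groups$id, coef, state = state, stateLabel = lab,
                    stringsAsFactors = FALSE)
  names(out)[seq_len(nc) + 1L] <- paste0("coef.", grouping@labels)
  out
}

#' Count the distinct states of a grouping
#'
#' Enumerates the state of every half-site group under *generic*
#' (algebraically independent) class weights and counts the distinct
#' values. Two states coincide under generic weights exactly when their
#' class-coefficient vectors coincide, so the count is computed exactly on
#' the integer coefficient vectors; no floating-point weights enter the
#' result.
#'
#' @param schema an [ElementSchema-class].
#' @param grouping a [StateGrouping-class] (its numeric weights are
#'   ignored; only the partition matters).
#' @return list with `nStates` (integer) and `census`, a data.frame of the
#'   distinct states (symbolic label, coefficient key, group count),
#'   ordered by a generic numeric realisation of the state so that the
#'   ladder runs from most negative to most positive.
#' @examples
#' sch <- builtinSchema("ERE13")
#' countDistinctStates(sch, signatureGrouping(sch, c(4, 1)))$nStates  # 3
#' countDistinctStates(sch, signatureGrouping(sch, c(1, 1, 1, 1, 1)))$nStates  # 51
#' @export
countDistinctStates <- function(schema, grouping) {
  groups <- enumerateHalfSiteGroups(schema)
  st <- stateOfGroup(groups, grouping)
  nc <- length(grouping@weights)
  coef <- as.matrix(st[, paste0("coef.", grouping@labels), drop = FALSE])
  key <- apply(coef, 1, paste, collapse = ",")
  ## order the ladder by the grouping's own weights, generic tie-break
  generic <- sqrt(c(2, 3, 5, 7, 11, 13))[seq_len(nc)]
  val <- drop(coef %*% grouping@weights)
  tie <- drop(coef %*% generic)
  census <- data.frame(key = key, stateLabel = st$stateLabel, value = val,
                       tie = tie, stringsAsFactors = FALSE)
  census <- census[!duplicated(census$key), ]
  census$count <- as.integer(table(key)[census$key])
  census <- census[order(census$value, census$tie), ]
  census$tie <- NULL
  rownames(census) <- NULL
  list(nStates = nrow(census), census = census)
}
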