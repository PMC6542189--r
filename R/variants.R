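## Variant element identifiers are the concatenation of "<position><base>"
## terms in ascending position order ("1T", "3A8C", ...); the consensus is
## "consensus". Parsing is unambiguous because a base letter terminates
## each term.

parseElementId <- function(ids) {
  m <- gregexpr("([0-9]+)([ACGT])", ids)
  terms <- regmatches(ids, m)
  lapply(seq_along(ids), function(i) {
    tt <- terms[[i]]
    if (identical(ids[i], "consensus") || length(tt) == 0L)
      return(list(pos = integer(0), base = character(0)))
    list(pos = as.integer(sub("[ACGT]$", "", tt)),
         base = sub("^[0-9]+", "", tt))
  })
}

makeElementId <- function(pos, base) {
  if (length(pos) == 0L) return("consensus")
  o <- order(pos)
  paste0(pos[o], base[o], collapse = "")
}

## Generate all variants whose substituted positions are exactly `posSets`
## (a list of integer vectors); one block per position set, bases cycling
## with the last position fastest. Workhorse for enumerateVariants() and
## groupMembers().
variantsForPositionSets <- function(schema, posSets) {
  cons <- primaryBases(schema)
  n <- nPrimary(schema)
  h <- n %/% 2L
  sp <- strrep("N", spacerLength(schema))
  out <- vector("list", length(posSets))
  for (j in seq_along(posSets)) {
    ps <- posSets[[j]]
    k <- length(ps)
    if (k == 0L) {
      out[[j]] <- data.frame(
        id = "consensus", k = 0L, pos = "", posMask = 0L,
        seq = consensusSequence(schema), stringsAsFactors = FALSE)
      next
    }
    alts <- lapply(ps, function(p) setdiff(DNA_BASES, cons[p]))
    ## expand.grid varies its first factor fastest; feed the positions in
    ## reverse so the *last* position cycles fastest, then restore order.
    grid <- expand.grid(rev(alts), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid <- as.matrix(grid[, rev(seq_len(k)), drop = FALSE])
    nr <- nrow(grid)
    mat <- matrix(rep(cons, each = nr), nrow = nr)
    mat[, ps] <- grid
    cols <- lapply(seq_len(n), function(i) mat[, i])
    seqs <- do.call(paste0, c(cols[seq_len(h)], list(sp), cols[(h + 1L):n]))
    idParts <- vector("list", 2L * k)
    for (i in seq_len(k)) {
      idParts[[2L * i - 1L]] <- rep(ps[i], nr)
      idParts[[2L * i]] <- grid[, i]
    }
    out[[j]] <- data.frame(
      id = do.call(paste0, idParts), k = k,
      pos = paste(ps, collapse = ","), posMask = positionMask(ps),
      seq = seqs, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Enumerate the k-substitution variants of a consensus element
#'
#' All DNA elements at Hamming distance exactly `k` from the consensus over
#' the primary positions (the spacer is never substituted). There are
#' `choose(n, k) * 3^k` such elements; iteration order is deterministic:
#' position sets in lexicographic order, then the three alternative bases
#' per position in alphabetical order with the last position cycling
#' fastest.
#'
#' @param schema an [ElementSchema-class].
#' @param k number of substitutions, `0 <= k <= n`.
#' @return data.frame with columns `id`, `k`, `pos` (comma-separated
#'   substituted positions), `posMask` (bitmask of positions), and `seq`
#'   (realized sequence, spacer rendered as `N`).
#' @examples
#' nrow(enumerateVariants(builtinSchema("ERE13"), 1))  # 30
#' @export
enumerateVariants <- function(schema, k) {
  n <- nPrimary(schema)
  k <- as.integer(k)
  if (k < 0L || k > n)
    stop("k must be between 0 and ", n, " for schema ", schemaName(schema))
  if (k == 0L) return(variantsForPositionSets(schema, list(integer(0))))
  posSets <- asplit(utils::combn(n, k), 2)
  variantsForPositionSets(schema, posSets)
}

#' Enumerate all variants up to a maximum level
#'
#' @param schema an [ElementSchema-class].
#' @param kMax maximum substitution count.
#' @return data.frame as [enumerateVariants()], rows for `k = 0..kMax`.
#' @export
elementUniverse <- function(schema, kMax) {
  do.call(rbind, lapply(0:kMax, function(k) enumerateVariants(schema, k)))
}

#' Number of k-substitution variants
#'
#' Closed-form count `choose(n, k) * 3^k` of elements at Hamming distance
#' exactly `k` from the consensus.
#'
#' @param schema an [ElementSchema-class].
#' @param k substitution count (vectorised).
#' @return numeric vector of counts.
#' @export
variantCount <- function(schema, k) {
  choose(nPrimary(schema), k) * 3^k
}

#' Reverse-complement of variant elements
#'
#' Maps a substitution at position `p` with base `b` to a substitution at
#' the palindromic partner `n + 1 - p` with `complement(b)`. The realized
#' sequence of the result is the biological reverse complement of the
#' input's realized sequence, and the substitution count `k` is preserved.
#' The consensus is its own reverse complement.
#'
#' @param schema an [ElementSchema-class].
#' @param ids character vector of element ids.
#' @return character vector of reverse-complement element ids.
#' @examples
#' rcElement(builtinSchema("ERE13"), "1T")  # "10A"
#' @export
rcElement <- function(schema, ids) {
  n <- nPrimary(schema)
  parsed <- parseElementId(ids)
  vapply(parsed, function(pb) {
    makeElementId(n + 1L - pb$pos, complementBase(pb$base))
  }, character(1))
}

#' Realized sequence of variant elements
#'
#' @param schema an [ElementSchema-class].
#' @param ids character vector of element ids.
#' @param spacer character used for the spacer positions.
#' @return character vector of realized sequences.
#' @export
realizeElement <- function(schema, ids, spacer = "N") {
  cons <- primaryBases(schema)
  n <- nPrimary(schema)
  h <- n %/% 2L
  sp <- strrep(spacer, spacerLength(schema))
  parsed <- parseElementId(ids)
  vapply(parsed, function(pb) {
    b <- cons
    b[pb$pos] <- pb$base
    paste0(paste(b[seq_len(h)], collapse = ""), sp,
           paste(b[(h + 1L):n], collapse = ""))
  }, character(1))
}
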