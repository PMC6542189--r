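#' Enumerate the half-site groups of a schema
#'
#' A half-site group is the set of variant elements sharing a given choice
#' of `n/2` fixed (consensus) primary positions, the remaining `n/2`
#' positions being free to vary. There are `choose(n, n/2)` groups (252 for
#' n = 10, 924 for n = 12). Each palindromic position pair is classified
#' relative to the fixed set:
#' \describe{
#'   \item{vacancy}{neither member fixed — the pair's consensus identity is
#'     absent from the element;}
#'   \item{double occupant}{both members fixed — the identity is specified
#'     twice;}
#'   \item{single}{exactly one member fixed.}
#' }
#' The number of vacancies always equals the number of double occupants.
#' Mapping the fixed set through the pair map `p <-> n + 1 - p` gives the
#' group's reverse-complement partner; a group equal to its own partner is
#' an innate palindrome (possible only when every pair is wholly fixed or
#' wholly vacant, i.e. for n = 12, never for n = 10).
#'
#' @param schema an [ElementSchema-class].
#' @return data.frame with one row per group: `id` (1-based, groups in
#'   lexicographic order of their fixed sets), `fixed` (e.g.
#'   `"1-2-3-4-5"`), `fixedMask`, `nV`, `nD`, `nS`, `vacPairs` / `dblPairs`
#'   (comma-separated pair labels), `vacLabel` / `dblLabel` (compact
#'   position-ID labels such as `"1V3"`, pairs identified by their lower
#'   member), `rcId` (id of the reverse-complement group), `innate`, and
#'   `representative` (`TRUE` for the lexicographically smaller member of
#'   each reverse-complement pair, and for innate groups).
#' @examples
#' g <- enumerateHalfSiteGroups(builtinSchema("ERE13"))
#' nrow(g)                     # 252
#' table(g$nV[g$representative])  # 16 / 80 / 30
#' @export
enumerateHalfSiteGroups <- function(schema) {
  n <- nPrimary(schema)
  if (n %% 2L != 0L) stop("schema must have an even number of primary positions")
  h <- n %/% 2L
  combs <- utils::combn(n, h)          # columns in lexicographic order
  ng <- ncol(combs)
  inF <- matrix(FALSE, ng, n)
  inF[cbind(rep(seq_len(ng), each = h), as.vector(combs))] <- TRUE
  ## pair occupancy count: 0 = vacancy, 1 = single, 2 = double occupant
  cnt <- inF[, seq_len(h), drop = FALSE] +
    inF[, n + 1L - seq_len(h), drop = FALSE]
  pl <- pairLabels(schema)
  fixedStr <- apply(combs, 2, paste, collapse = "-")
  pairJoin <- function(m, val, what) {
    apply(m == val, 1, function(z) paste(what[z], collapse = ","))
  }
  vacPairs <- pairJoin(cnt, 0L, pl)
  dblPairs <- pairJoin(cnt, 2L, pl)
  nV <- rowSums(cnt == 0L)
  nD <- rowSums(cnt == 2L)
  nS <- h - nV - nD
  compactLabel <- function(nX, m, val) {
    lows <- apply(m == val, 1, function(z) paste(which(z), collapse = "."))
    paste0(nX, ifelse(val == 0L, "V", "D"), lows)
  }
  vacLabel <- compactLabel(nV, cnt, 0L)
  dblLabel <- compactLabel(nD, cnt, 2L)
  ## reverse-complement partner: map the fixed set through the pair map
  rcFixedStr <- apply(combs, 2, function(f) {
    paste(sort(n + 1L - f), collapse = "-")
  })
  idx <- stats::setNames(seq_len(ng), fixedStr)
  rcId <- unname(idx[rcFixedStr])
  innate <- rcId == seq_len(ng)
  fixedMask <- apply(combs, 2, positionMask)
  data.frame(
    id = seq_len(ng), fixed = fixedStr, fixedMask = fixedMask,
    nV = nV, nD = nD, nS = nS,
    vacPairs = vacPairs, dblPairs = dblPairs,
    vacLabel = vacLabel, dblLabel = dblLabel,
    rcId = rcId, innate = innate,
    representative = seq_len(ng) <= rcId,
    stringsAsFactors = FALSE)
}

#' Level-k members of a half-site group
#'
#' All elements at substitution level `k` whose substituted positions fall
#' entirely within the group's non-fixed positions; there are
#' `choose(n/2, k) * 3^k` of them, and summing over `k = 0..n/2` gives
#' `4^(n/2)` elements per group (1,024 for n = 10; 4,096 for n = 12).
#'
#' @param schema an [ElementSchema-class].
#' @param group one row of [enumerateHalfSiteGroups()] output, or a vector
#'   of fixed positions.
#' @param k substitution level, `0 <= k <= n/2`.
#' @return data.frame as [enumerateVariants()].
#' @export
groupMembers <- function(schema, group, k) {
  n <- nPrimary(schema)
  h <- n %/% 2L
  k <- as.integer(k)
  if (k < 0L || k > h)
    stop("k must be between 0 and ", h, " (at most the free positions)")
  fixed <- if (is.data.frame(group)) {
    as.integer(strsplit(group$fixed[1], "-")[[1]])
  } else as.integer(group)
  free <- setdiff(seq_len(n), fixed)
  if (length(free) != h) stop("group must fix exactly n/2 positions")
  posSets <- if (k == 0L) list(integer(0)) else
    asplit(utils::combn(free, k), 2)
  variantsForPositionSets(schema, posSets)
}

#' Display order of the half-site groups
#'
#' Orders the groups for the mirror-symmetric signal-to-noise display: the
#' left block holds the representatives sorted by vacancy count (zero, one,
#' two vacancies, left to right), then by the ranks of their vacancy pairs
#' under the supplied hierarchy, then by double-occupant pair ranks, then
#' lexicographically by fixed set; the right block holds the
#' reverse-complements of the left block in reversed order, so positions
#' `i` and `total + 1 - i` are always reverse-complement partners. For
#' n = 12 the innate palindromes form a centre block between the two
#' (sorted by the same keys).
#'
#' @param groups output of [enumerateHalfSiteGroups()].
#' @param hierarchy character vector of pair labels, most-preferred first;
#'   must be a permutation of the schema's pairs (see
#'   [vacancyHierarchy()]).
#' @return integer vector of group `id`s in display order.
#' @examples
#' g <- enumerateHalfSiteGroups(builtinSchema("ERE13"))
#' ord <- axisOrder(g, vacancyHierarchy("ERE13"))
#' g$fixed[ord[1]]    # "1-2-3-4-5"
#' g$fixed[ord[252]]  # "6-7-8-9-10"
#' @export
axisOrder <- function(groups, hierarchy) {
  h <- nchar(gsub("[^-]", "", groups$fixed[1])) + 1L  # n/2 fixed positions
  allPairs <- sort(unique(unlist(strsplit(
    groups$vacPairs[groups$vacPairs != ""], ","))))
  ## hierarchy must be a permutation of the schema's pair labels
  pairsSeen <- unique(unlist(strsplit(
    paste(groups$vacPairs, groups$dblPairs, sep = ","), ",")))
  pairsSeen <- setdiff(pairsSeen, "")
  if (length(hierarchy) != h || anyDuplicated(hierarchy) ||
      !all(pairsSeen %in% hierarchy))
    stop("hierarchy must be a permutation of the schema's palindromic pairs")
  rank <- stats::setNames(seq_along(hierarchy), hierarchy)
  rankKey <- function(pairStr) {
    ## fixed-width sortable string of hierarchy ranks, padded with 9s
    vapply(strsplit(pairStr, ","), function(p) {
      p <- p[p != ""]
      r <- sort(rank[p])
      paste(formatC(c(r, rep(9L, h - length(r))), width = 2, flag = "0"),
            collapse = "")
    }, character(1))
  }
  fixedKey <- vapply(strsplit(groups$fixed, "-"), function(f) {
    paste(formatC(as.integer(f), width = 2, flag = "0"), collapse = "")
  }, character(1))
  key <- order(groups$nV, rankKey(groups$vacPairs), rankKey(groups$dblPairs),
               fixedKey)
  sorted <- groups$id[key]
  isRep <- groups$representative[key]
  isInn <- groups$innate[key]
  left <- sorted[isRep & !isInn]
  centre <- sorted[isInn]
  right <- rev(groups$rcId[left])
  c(left, centre, right)
}
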