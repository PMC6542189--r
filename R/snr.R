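#' Expected element count under the random-genome model
#'
#' A specific n-position element (spacer unconstrained) matches a random
#' position with probability `4^-n`, i.e. once every `4^n` nucleotides
#' (1,048,576 for n = 10; 16,777,216 for n = 12). Across `N` peaks of
#' nominal length `L` the expectation for a unit aggregating `m` elements
#' is `lambda = N * L * m / 4^n`. This nominal-window convention (the
#' window count is not reduced by `footprint - 1`) is the one that
#' reproduces the published significance-threshold pairs; see
#' [snrProfile()] for the alternative.
#'
#' @param N number of peaks.
#' @param L nominal peak length (nt).
#' @param schema an [ElementSchema-class] (supplies `n`).
#' @param m number of elements aggregated in the unit (1 for a single
#'   element; `choose(n/2, k) * 3^k` for a group at level k;
#'   `choose(n, k) * 3^k` for a whole level).
#' @return expected count `lambda`.
#' @examples
#' expectedCount(76163, 146, builtinSchema("ERE13"))  # ~10.6
#' @export
expectedCount <- function(N, L, schema, m = 1) {
  if (any(c(N, L, m) <= 0)) stop("N, L and m must be positive")
  N * L * m / 4^nPrimary(schema)
}

#' One-tailed Poisson significance thresholds on the S/N scale
#'
#' For expectation `lambda`, the bounds are `Q(p) / lambda` and
#' `Q(1 - p) / lambda`, where `Q(q)` is the smallest integer whose Poisson
#' CDF at `lambda` reaches `q` (i.e. `stats::qpois`). An observed
#' signal-to-noise ratio outside `[lower, upper]` occurs by chance with
#' probability below `p` in each tail. When `ppois(0, lambda) >= p` the
#' lower bound is exactly 0. Bounds depend only on `(lambda, p)`, never on
#' the observed count, and bracket 1.
#'
#' @param lambda expected count (> 0).
#' @param p one-tailed significance level, `0 < p < 0.5`.
#' @return named numeric `c(lower, upper)` (unrounded; the published
#'   two-decimal values use [roundHalfUp()]).
#' @examples
#' roundHalfUp(poissonThresholds(76163 * 146 / 4^10), 2)  # 0.19, 2.07
#' @export
poissonThresholds <- function(lambda, p = 0.001) {
  if (lambda <= 0) stop("lambda must be positive")
  if (p <= 0 || p >= 0.5) stop("p must be in (0, 0.5)")
  c(lower = stats::qpois(p, lambda) / lambda,
    upper = stats::qpois(1 - p, lambda) / lambda)
}

## Internal: one S/N record block from observed counts and lambdas.
snrRecords <- function(observed, lambda, p) {
  lower <- vapply(lambda, function(l) stats::qpois(p, l) / l, numeric(1))
  upper <- vapply(lambda, function(l) stats::qpois(1 - p, l) / l, numeric(1))
  data.frame(observed = observed, lambda = lambda,
             snr = observed / lambda, lower = lower, upper = upper)
}

#' Signal-to-noise profiles over elements, groups and levels
#'
#' Converts occurrence counts inside a peak set into signal-to-noise
#' ratios `observed / lambda` with one-tailed Poisson bounds, for three
#' display units: per substitution level, per half-site group x level
#' (ordered along the mirror-symmetric display axis), and per
#' variant-position combination x level.
#'
#' Two window conventions are available for `lambda`:
#' `windows = "nominal"` uses `N * L` (the convention behind the
#' published threshold pairs); `windows = "effective"` uses
#' `sum(L_i - footprint + 1)`, the exact number of positions where an
#' element can be fully contained, which is the correct null expectation
#' for containment counting (the two differ by a factor
#' `~ 1 - (footprint - 1)/L`).
#'
#' @param counts output of [countInPeaks()] with an `elements` table.
#' @param peaks `GRanges` of the peak set the counts came from.
#' @param schema an [ElementSchema-class].
#' @param groups optional [enumerateHalfSiteGroups()] output; required for
#'   the group profile.
#' @param hierarchy optional pair-label hierarchy for [axisOrder()];
#'   defaults to the natural pair order.
#' @param p one-tailed significance level.
#' @param windows `"nominal"` or `"effective"` (see Details).
#' @return list with data.frames `byLevel`, `byGroup` (columns include
#'   `axis_pos`, the display position) and `byPositions`.
#' @export
snrProfile <- function(counts, peaks, schema, groups = NULL,
                       hierarchy = NULL, p = 0.001,
                       windows = c("nominal", "effective")) {
  windows <- match.arg(windows)
  ps <- peakStats(peaks)
  W <- if (windows == "nominal") ps$N * as.numeric(ps$L) else
    sum(pmax(as.numeric(GenomicRanges::width(peaks)) - footprint(schema) + 1, 0))
  denom <- 4^nPrimary(schema)
  h <- nPrimary(schema) %/% 2L
  byLevel <- aggregateByLevel(counts, schema)
  byLevel <- cbind(byLevel[, c("k", "m")],
                   snrRecords(byLevel$count, W * byLevel$m / denom, p))
  byPos <- aggregateByPositions(counts)
  byPos <- cbind(byPos[, c("k", "pos", "m")],
                 snrRecords(byPos$count, W * byPos$m / denom, p))
  byGroup <- NULL
  if (!is.null(groups)) {
    gm <- aggregateByGroup(counts, groups)
    ord <- if (is.null(hierarchy)) groups$id else axisOrder(groups, hierarchy)
    ks <- as.integer(colnames(gm))
    blocks <- lapply(ks, function(k) {
      m <- choose(h, k) * 3^k
      obs <- gm[as.character(ord), as.character(k)]
      cbind(data.frame(group_id = ord, axis_pos = seq_along(ord), k = k,
                       m = m),
            snrRecords(obs, rep(W * m / denom, length(ord)), p))
    })
    byGroup <- do.call(rbind, blocks)
    rownames(byGroup) <- NULL
  }
  list(byLevel = byLevel, byGroup = byGroup, byPositions = byPos,
       N = ps$N, L = ps$L, windows = windows, p = p)
}

#' Scale invariance of level-aggregate S/N ratios
#'
#' The relative S/N values between substitution levels are expected to be
#' invariant to uniform subsampling of the peak universe. Compares the
#' log-ratios of level-aggregate counts (lambda cancels within a peak
#' set) between a full and a subsampled table; each log-ratio difference
#' is judged against `nSD` Poisson standard deviations
#' `sqrt(1/c_k + 1/c_0)` summed over both tables.
#'
#' @param countsFull,countsSub [countInPeaks()] outputs for the full and
#'   subsampled peak sets.
#' @param schema an [ElementSchema-class].
#' @param baseline level used as the ratio denominator (default 0).
#' @param nSD tolerance in standard deviations.
#' @return data.frame per level: log-ratios, difference, tolerance and an
#'   `ok` flag; attribute `insufficient` is `TRUE` when a table has too
#'   little data to compare.
#' @export
scaleInvariance <- function(countsFull, countsSub, schema, baseline = 0,
                            nSD = 3) {
  lf <- aggregateByLevel(countsFull, schema)
  ls <- aggregateByLevel(countsSub, schema)
  ks <- intersect(lf$k, ls$k)
  ks <- setdiff(ks, baseline)
  cf0 <- lf$count[lf$k == baseline]
  cs0 <- ls$count[ls$k == baseline]
  insufficient <- length(cf0) == 0L || length(cs0) == 0L ||
    sum(ls$count) == 0 || cf0 == 0 || cs0 == 0
  if (insufficient) {
    out <- data.frame(k = integer(0), logRatioFull = numeric(0),
                      logRatioSub = numeric(0), diff = numeric(0),
                      tol = numeric(0), ok = logical(0))
    attr(out, "insufficient") <- TRUE
    return(out)
  }
  cf <- lf$count[match(ks, lf$k)]
  cs <- ls$count[match(ks, ls$k)]
  rf <- log(cf / cf0)
  rs <- log(cs / cs0)
  tol <- nSD * sqrt(1 / pmax(cf, 1) + 1 / cf0 + 1 / pmax(cs, 1) + 1 / cs0)
  out <- data.frame(k = ks, logRatioFull = rf, logRatioSub = rs,
                    diff = rs - rf, tol = tol,
                    ok = is.finite(rs - rf) & abs(rs - rf) <= tol)
  attr(out, "insufficient") <- FALSE
  out
}
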