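#' Structural plateau assignment of half-site groups
#'
#' Assigns every half-site group to its discrete binding-state plateau
#' under a [StateGrouping-class]. Membership is *structural* — determined
#' by which weighted pairs are vacant or doubly occupied in the group, via
#' [stateOfGroup()] — not clustered from empirical values, which is what
#' makes the plateau censuses exact integers (6/60/120/60/6 for the
#' estrogen grouping, 56/140/56 for the ketosteroid grouping).
#'
#' @param groups output of [enumerateHalfSiteGroups()].
#' @param grouping a [StateGrouping-class] over the same schema.
#' @return data.frame from [stateOfGroup()]: one row per group with
#'   coefficient columns, numeric `state` and symbolic `stateLabel`.
#' @export
assignPlateaus <- function(groups, grouping) {
  h <- nPrimary(grouping@schema) %/% 2L
  if (nchar(gsub("[^-]", "", groups$fixed[1])) + 1L != h)
    stop("grouping schema does not match the group table")
  stateOfGroup(groups, grouping)
}

#' Summarise empirical S/N values per plateau
#'
#' Computes, for each plateau, the member count, mean, standard deviation
#' (sample and population) and the difference from the zero-state plateau
#' mean, then estimates the algebraic step variables (X, and Y, Z, ... for
#' multi-class groupings) by least squares of the per-group S/N values on
#' the class coefficients.
#'
#' @param membership output of [assignPlateaus()].
#' @param snr numeric vector of per-group S/N values, aligned with
#'   `membership` rows (typically the level-1 group profile).
#' @param grouping the [StateGrouping-class] used for the assignment.
#' @return list with `summary` (per-plateau data.frame: `state`,
#'   `stateLabel`, `n`, `mean`, `sd`, `sdPop`, `diffFromZero`),
#'   `estimates` (named vector of fitted step variables), `se` (their
#'   standard errors) and `fit` (the underlying `lm`).
#' @export
quantifyPlateaus <- function(membership, snr, grouping) {
  if (length(snr) != nrow(membership))
    stop("snr must supply one value per group")
  coefCols <- paste0("coef.", grouping@labels)
  ## reference class: zero-weight class if present, else the last
  ref <- if (any(grouping@weights == 0)) {
    which(grouping@weights == 0)[1]
  } else length(grouping@weights)
  useCols <- coefCols[-ref]
  key <- membership$state
  plateaus <- sort(unique(key))
  stats_ <- lapply(plateaus, function(s) {
    v <- snr[key == s]
    data.frame(state = s,
               stateLabel = membership$stateLabel[key == s][1],
               n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               sdPop = sqrt(mean((v - mean(v))^2)),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, stats_)
  zeroMean <- summary$mean[summary$state == 0]
  summary$diffFromZero <- if (length(zeroMean))
    summary$mean - zeroMean else NA_real_
  ## least-squares step estimation on the class coefficients
  symNames <- c("X", "Y", "Z", "W", "V")[seq_along(useCols)]
  if (length(useCols)) {
    df <- data.frame(snr = snr,
                     membership[, useCols, drop = FALSE])
    names(df)[-1] <- symNames
    fit <- stats::lm(snr ~ ., data = df)
    ## noiseless state-linear input is legitimate; silence the
    ## "essentially perfect fit" note its summary would emit
    cf <- suppressWarnings(summary(fit)$coefficients)
    estimates <- stats::setNames(cf[symNames, "Estimate"], symNames)
    se <- stats::setNames(cf[symNames, "Std. Error"], symNames)
  } else {
    fit <- NULL
    estimates <- se <- numeric(0)
  }
  list(summary = summary, estimates = estimates, se = se, fit = fit)
}

#' Residuals of the plateau equation system
#'
#' Checks that the fitted plateau means satisfy the grouping's algebra:
#' every plateau mean should equal the zero-plateau baseline plus the
#' coefficient combination of the fitted step variables (e.g.
#' `AB - CC = Y + Z` in the three-variable grouping). On noiseless
#' state-linear input the residuals are identically zero; under additive
#' noise of scale `sigma` they scale with `sigma`.
#'
#' @param quantified output of [quantifyPlateaus()].
#' @param membership the [assignPlateaus()] table that produced it.
#' @param grouping the [StateGrouping-class].
#' @return list with `residuals` (per-plateau data.frame: observed mean,
#'   predicted mean, residual) and `maxResidual`.
#' @export
algebraicChecks <- function(quantified, membership, grouping) {
  summary <- quantified$summary
  est <- quantified$estimates
  coefCols <- paste0("coef.", grouping@labels)
  ref <- if (any(grouping@weights == 0)) {
    which(grouping@weights == 0)[1]
  } else length(grouping@weights)
  useCols <- coefCols[-ref]
  intercept <- if (!is.null(quantified$fit))
    unname(stats::coef(quantified$fit)[1]) else mean(summary$mean)
  pred <- vapply(summary$state, function(s) {
    row <- membership[match(s, membership$state), useCols, drop = FALSE]
    intercept + sum(as.numeric(row) * est)
  }, numeric(1))
  res <- data.frame(state = summary$state, stateLabel = summary$stateLabel,
                    observed = summary$mean, predicted = pred,
                    residual = summary$mean - pred)
  list(residuals = res, maxResidual = max(abs(res$residual)))
}
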