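#' The first-derivative test: per-year probability of non-negative growth
#'
#' Computes, for every assessable year, the proportion of posterior draws in
#' which the indicator's log growth rate into that year is at or above zero:
#' \eqn{p_t = S^{-1}\sum_s 1[\eta_t^{(s)} \ge 0]}. Draws exactly at zero
#' count as meeting the target (the ">= 0" convention). Values above 0.5 mean
#' an increasing trend is more likely than a decreasing one.
#'
#' Unconverged fits are refused unless \code{force = TRUE}.
#'
#' @param fit an [IndicatorFit-class].
#' @param force proceed despite a failed convergence flag.
#' @return A [TestResult-class] over the fit's assessable years (all fitted
#'   years except the base year).
#' @examples
#' \donttest{
#' ds <- simulateGrowthSeries(simParams(1.03, nYears = 12), 5, baseValues = 100)
#' fit <- fitIndicator(ds, nKnots = 4, mcmc = shortMcmc())
#' pGeq0(derivativeProbabilities(fit))
#' }
#' @export
derivativeProbabilities <- function(fit, force = FALSE) {
  stopifnot(is(fit, "IndicatorFit"))
  if (!fit@converged && !force)
    stop("fit is not converged; inspect fitDiagnostics() or use force = TRUE")
  p <- colMeans(fit@etaDraws >= 0)
  methods::new("TestResult",
    years = fit@years[-1L], pGeq0 = as.numeric(p),
    nDraws = nrow(fit@etaDraws),
    fitMeta = list(nKnots = fit@nKnots, seed = fit@mcmc@seed,
                   converged = fit@converged))
}

#' Decide a halt-the-loss target for a given year
#'
#' The target is met when the tested probability that the indicator's growth
#' rate into the target year is >= 0 reaches the threshold (the comparison is
#' \code{p >= threshold}, so a probability exactly at the threshold counts as
#' met). When the target year is the final year with data, the decision is
#' flagged as interim: end-of-series smoothing means later years of data can
#' retrospectively change the assessment, so it should be revisited once
#' subsequent data are available.
#'
#' @param result a [TestResult-class].
#' @param targetYear the policy target year; must be an assessable year.
#' @param threshold acceptance threshold in (0, 1), set in advance and ideally
#'   calibrated by simulation ([runScenario()], [errorRateTable()]).
#' @return A list: \code{met} (logical), \code{p}, \code{threshold},
#'   \code{targetYear}, \code{interim} (TRUE when targetYear is the final data
#'   year), \code{converged}.
#' @export
decideTarget <- function(result, targetYear, threshold) {
  stopifnot(is(result, "TestResult"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  targetYear <- as.integer(targetYear)
  idx <- match(targetYear, result@years)
  if (is.na(idx))
    stop("target year ", targetYear, " is outside the assessable years (",
         min(result@years), "-", max(result@years), ")")
  p <- result@pGeq0[idx]
  list(met = p >= threshold, p = p, threshold = threshold,
       targetYear = targetYear,
       interim = targetYear == max(result@years),
       converged = isTRUE(result@fitMeta$converged))
}

#' Retrospective target assessment as later years of data accrue
#'
#' Emulates the situation where a target-year assessment is revisited as data
#' for subsequent years arrive. A simulated future is appended to the history
#' once; the resulting series is then truncated at each horizon from the
#' target year up to \code{targetYear + maxExtraYears}, and at every horizon
#' the full pipeline is re-run (pre-smooth, refit with knots recomputed from
#' the current timespan at a fixed factor, test), reporting the probability
#' that growth into the target year is >= 0. The data for the shared years
#' are identical across horizons, so any change in the target-year assessment
#' is purely an effect of the added years.
#'
#' @param history a [SpeciesDataset-class] ending at or before the target year.
#' @param params [SimParams-class] for the appended years; its nYears is
#'   overridden to reach \code{targetYear + maxExtraYears}.
#' @param targetYear year to assess (>= final history year).
#' @param maxExtraYears number of additional data years to explore (>= 0).
#' @param knotsFactor indicator knots per year of timespan at each refit.
#' @param presmoothFactor species-level pre-smoothing factor.
#' @param mcmc a [McmcConfig-class].
#' @param seed seed for the single appended simulation.
#' @param ... further arguments passed to [fitIndicator()] (e.g. \code{obsSd},
#'   \code{gParam}).
#' @return A data.frame with one row per data horizon: \code{dataEndYear},
#'   \code{pTarget}, \code{etaMeanTarget} (posterior-mean log growth into the
#'   target year), \code{nKnots}, \code{converged}, \code{error}.
#' @export
retrospectiveAssessment <- function(history, params, targetYear,
                                    maxExtraYears, knotsFactor = 0.17,
                                    presmoothFactor = 0.3,
                                    mcmc = shortMcmc(), seed = params@seed,
                                    ...) {
  stopifnot(is(history, "SpeciesDataset"), is(params, "SimParams"))
  targetYear <- as.integer(targetYear)
  lastHist <- max(datasetYears(history))
  if (targetYear < lastHist)
    stop("targetYear must be at or after the final history year")
  if (maxExtraYears < 0) stop("maxExtraYears must be >= 0")
  nApp <- (targetYear - lastHist) + maxExtraYears
  full <- if (nApp > 0) {
    p2 <- simParams(params@meanGrowth, params@sdInterspecific,
                    params@sdInterannual, params@sdMeasurement,
                    nYears = nApp, seed = seed)
    appendSimulated(history, p2, seed = seed)
  } else history
  out <- data.frame()
  for (h in 0:maxExtraYears) {
    endYear <- targetYear + h
    row <- data.frame(dataEndYear = endYear, pTarget = NA_real_,
                      etaMeanTarget = NA_real_, nKnots = NA_integer_,
                      converged = NA, error = NA_character_)
    res <- try({
      ds <- windowYears(full, to = endYear)
      sm <- presmoothDataset(ds, presmoothFactor)
      k <- numKnots(ncol(sm), knotsFactor)
      fit <- fitIndicator(sm, nKnots = k, mcmc = mcmc, ...)
      tr <- derivativeProbabilities(fit, force = TRUE)
      idx <- match(targetYear, tr@years)
      row$pTarget <- tr@pGeq0[idx]
      row$etaMeanTarget <-
        mean(etaDraws(fit)[, match(targetYear, fit@years[-1L])])
      row$nKnots <- k
      row$converged <- fit@converged
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      row$error <- conditionMessage(attr(res, "condition"))
    out <- rbind(out, row)
  }
  out
}
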