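#' Run a replicated simulation scenario
#'
#' Replicates the calibration experiment for one scenario: for each run, a
#' fresh simulated future is appended to the (shared) history, every species
#' series is pre-smoothed, the indicator is fitted at each smoothing level in
#' \code{knotsList}, and the first-derivative test is evaluated. Per-run
#' seeds are derived deterministically from the master seed, so the whole
#' summary is reproducible bit-for-bit. Runs whose fit fails or does not
#' converge are excluded from the aggregates and reported in
#' \code{@failures}, never silently imputed or re-seeded.
#'
#' Aggregates per smoothing level: the average probability that growth is
#' >= 0 in each year, and the distribution of final-year probabilities over
#' runs in 5-percentage-point bins ([finalYearHistogram()]).
#'
#' @param scn a [Scenario-class].
#' @param mcmc a [McmcConfig-class]; per-run chain seeds derive from the
#'   scenario's master seed, not from \code{mcmc@seed}.
#' @return An [ExperimentSummary-class].
#' @examples
#' \donttest{
#' scn <- scenario(historyProfile(10, 15, 0.99, label = "demo"),
#'                 simParams(1.03, nYears = 5), knotsList = 5L,
#'                 nRuns = 2L, masterSeed = 7L)
#' summary <- runScenario(scn, mcmc = shortMcmc())
#' }
#' @export
runScenario <- function(scn, mcmc = shortMcmc()) {
  stopifnot(is(scn, "Scenario"), is(mcmc, "McmcConfig"))
  methods::validObject(scn)
  history <- if (is(scn@history, "HistoryProfile"))
    generateHistory(scn@history, seed = substreamSeed(scn@masterSeed, 0L))
  else scn@history
  perRun <- data.frame()
  failures <- data.frame(run = integer(), knots = integer(),
                         reason = character())
  for (r in seq_len(scn@nRuns)) {
    runSeed <- substreamSeed(scn@masterSeed, r)
    ds <- appendSimulated(history, scn@sim, seed = runSeed)
    sm <- presmoothDataset(ds, scn@presmoothFactor)
    for (k in scn@knotsList) {
      rcfg <- mcmcConfig(nChains = mcmc@nChains, nDraws = mcmc@nDraws,
                         nWarmup = mcmc@nWarmup, nAdapt = mcmc@nAdapt,
                         seed = substreamSeed(runSeed, k),
                         rhatThreshold = mcmc@rhatThreshold)
      res <- try({
        fit <- fitIndicator(sm, nKnots = k, mcmc = rcfg)
        if (!fit@converged) stop("fit did not converge")
        tr <- derivativeProbabilities(fit)
        data.frame(run = r, knots = k, year = tr@years, p = tr@pGeq0)
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        failures <- rbind(failures, data.frame(
          run = r, knots = k,
          reason = conditionMessage(attr(res, "condition"))))
      } else perRun <- rbind(perRun, res)
    }
  }
  finalYear <- max(datasetYears(history)) + scn@sim@nYears
  if (!nrow(perRun))
    perRun <- data.frame(run = integer(), knots = integer(),
                         year = integer(), p = numeric())
  finalYearP <- perRun[perRun$year == finalYear, c("run", "knots", "p")]
  rownames(finalYearP) <- NULL
  meanP <- if (nrow(perRun))
    stats::aggregate(p ~ knots + year, data = perRun, FUN = mean)
  else data.frame(knots = integer(), year = integer(), p = numeric())
  names(meanP)[names(meanP) == "p"] <- "meanP"
  hist <- lapply(split(finalYearP$p, finalYearP$knots), finalYearHistogram)
  methods::new("ExperimentSummary",
    perRun = perRun, finalYearP = finalYearP, meanPByYear = meanP,
    histogram = hist, failures = failures, scenario = scn)
}

#' Histogram of final-year test outcomes in 5-point bins
#'
#' Bins probabilities into 20 five-percentage-point bins over [0\%, 100\%].
#' Bins are half-open \code{[lo, hi)} except the last, \code{[95, 100]},
#' which is closed so that a probability of exactly 1 is counted.
#'
#' @param p numeric vector of probabilities in [0, 1].
#' @param binWidth bin width on the probability scale (default 0.05).
#' @return Named integer vector of bin counts summing to \code{length(p)}.
#' @examples
#' finalYearHistogram(c(0.02, 0.03, 0.99))
#' @export
finalYearHistogram <- function(p, binWidth = 0.05) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  nb <- as.integer(round(1 / binWidth))
  # round before flooring so that boundary values (0.05, 0.95, ...) whose
  # floating-point quotient falls a hair below an integer bin correctly
  idx <- pmin(floor(round(p / binWidth, 9)) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  lo <- round(100 * binWidth * (seq_len(nb) - 1L))
  hi <- round(100 * binWidth * seq_len(nb))
  names(counts) <- paste0("[", lo, ",", hi, ifelse(seq_len(nb) < nb, ")", "]"))
  counts
}

#' False-negative / false-positive error rates over a threshold grid
#'
#' Given two experiment summaries with known, opposite truths — one simulated
#' under a non-negative trend (target truly met) and one under a negative
#' trend (decline truly continuing) — computes, for each acceptance threshold
#' \eqn{\theta}: the false-negative rate, the fraction of positive-truth runs
#' whose final-year probability falls below \eqn{\theta}; and the
#' false-positive rate, the fraction of negative-truth runs at or above
#' \eqn{\theta}. FNR is non-decreasing and FPR non-increasing in
#' \eqn{\theta} by construction. Both summaries must share smoothing levels
#' and final year.
#'
#' @param summaryPos [ExperimentSummary-class] with \code{truthSign}
#'   "positive".
#' @param summaryNeg [ExperimentSummary-class] with \code{truthSign}
#'   "negative".
#' @param thresholds grid of thresholds in (0, 1); default 0.05 steps.
#' @return data.frame (knots, threshold, fnr, fpr).
#' @export
errorRateTable <- function(summaryPos, summaryNeg,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(is(summaryPos, "ExperimentSummary"),
            is(summaryNeg, "ExperimentSummary"))
  if (summaryPos@scenario@truthSign != "positive" ||
      summaryNeg@scenario@truthSign != "negative")
    stop("summaryPos/summaryNeg must have positive/negative truthSign")
  kPos <- sort(unique(summaryPos@finalYearP$knots))
  kNeg <- sort(unique(summaryNeg@finalYearP$knots))
  if (!identical(kPos, kNeg))
    stop("the two summaries trial different smoothing levels")
  fyPos <- max(summaryPos@perRun$year)
  fyNeg <- max(summaryNeg@perRun$year)
  if (fyPos != fyNeg)
    stop("the two summaries end in different years")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly between 0 and 1")
  out <- data.frame()
  for (k in kPos) {
    pp <- summaryPos@finalYearP$p[summaryPos@finalYearP$knots == k]
    pn <- summaryNeg@finalYearP$p[summaryNeg@finalYearP$knots == k]
    for (th in thresholds)
      out <- rbind(out, data.frame(knots = k, threshold = th,
                                   fnr = mean(pp < th), fpr = mean(pn >= th)))
  }
  out
}
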