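#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats rnorm sd quantile median var coef fitted lm predict setNames
#' @importFrom utils read.csv write.csv
NULL

#' SpeciesDataset: a species-by-year table of abundance indices
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' species x year matrix of strictly positive abundance indices in the
#' \code{"values"} assay, optionally a matrix of log-scale standard errors in
#' the \code{"se"} assay, calendar years in \code{colData()$year}, and a
#' provenance record (how the data were generated or loaded) in
#' \code{metadata()}.
#'
#' Years must be strictly consecutive; every value must be positive; standard
#' errors, when present, must be non-negative and match the value matrix in
#' shape.
#'
#' @seealso [speciesDataset()] for the user-facing constructor,
#'   [abundanceValues()], [datasetYears()], [speciesIds()].
#' @export
setClass("SpeciesDataset", contains = "SummarizedExperiment")

setValidity("SpeciesDataset", function(object) {
  msg <- character()
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  else {
    v <- SummarizedExperiment::assay(object, "values")
    if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
    else if (any(!is.finite(v)) || any(v <= 0))
      msg <- c(msg, "all abundance values must be finite and > 0")
  }
  if (!"year" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'year' column")
  else {
    yr <- SummarizedExperiment::colData(object)$year
    if (ncol(object) > 1L && !all(diff(yr) == 1L))
      msg <- c(msg, "years must be strictly consecutive and increasing")
  }
  if ("se" %in% SummarizedExperiment::assayNames(object)) {
    s <- SummarizedExperiment::assay(object, "se")
    if (any(!is.finite(s)) || any(s < 0))
      msg <- c(msg, "standard errors must be finite and >= 0")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "species identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Simulation parameters for species growth series
#'
#' Defines the generative model for simulated species abundance series: a
#' common per-annum multiplicative growth rate plus three log-scale variability
#' components. Per species \eqn{i}, a constant deviation
#' \eqn{a_i \sim N(0, \sigma_{is}^2)} (interspecific); per species-year, a
#' deviation \eqn{b_{it} \sim N(0, \sigma_{ia}^2)} (interannual); the latent
#' log abundance follows
#' \eqn{x_{it} = x_{i,t-1} + \ln g + a_i + b_{it}} and the observed log value
#' adds measurement noise \eqn{e_{it} \sim N(0, \sigma_{me}^2)} that is not
#' propagated into the latent walk.
#'
#' @slot meanGrowth per-annum multiplicative growth rate \eqn{g} (> 0), e.g.
#'   1.03 for +3\% per year.
#' @slot sdInterspecific SD (log scale, per annum) of species-level deviations
#'   from the common growth rate.
#' @slot sdInterannual SD (log scale) of year-by-species growth deviations.
#' @slot sdMeasurement SD (log scale) of observation noise.
#' @slot nYears number of simulated years (>= 1).
#' @slot seed integer RNG seed.
#' @export
setClass("SimParams", representation(
  meanGrowth      = "numeric",
  sdInterspecific = "numeric",
  sdInterannual   = "numeric",
  sdMeasurement   = "numeric",
  nYears          = "integer",
  seed            = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (length(object@meanGrowth) != 1L || !is.finite(object@meanGrowth) ||
      object@meanGrowth <= 0)
    msg <- c(msg, "meanGrowth must be a single positive number")
  for (nm in c("sdInterspecific", "sdInterannual", "sdMeasurement")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, paste0(nm, " must be a single non-negative number"))
  }
  if (length(object@nYears) != 1L || is.na(object@nYears) || object@nYears < 1L)
    msg <- c(msg, "nYears must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Profile of a synthetic multi-decade history
#'
#' Describes a synthetic historical dataset: a declining (or otherwise)
#' multi-species collection of abundance index series standing in for real
#' multi-decade monitoring data. The variability fields have the same meaning
#' as in [SimParams()].
#'
#' @slot nSpecies number of species (>= 2).
#' @slot nYears number of historical years (>= 2).
#' @slot meanGrowth per-annum multiplier of the historical trend (typically
#'   < 1, i.e. declining).
#' @slot sdInterspecific,sdInterannual,sdMeasurement log-scale SDs as in
#'   [SimParams()].
#' @slot baseAbundance starting index value per species (> 0).
#' @slot startYear first calendar year of the history.
#' @slot label free-text tag, e.g. "bird-like".
#' @export
setClass("HistoryProfile", representation(
  nSpecies        = "integer",
  nYears          = "integer",
  meanGrowth      = "numeric",
  sdInterspecific = "numeric",
  sdInterannual   = "numeric",
  sdMeasurement   = "numeric",
  baseAbundance   = "numeric",
  startYear       = "integer",
  label           = "character"
))

setValidity("HistoryProfile", function(object) {
  msg <- character()
  if (object@nSpecies < 2L) msg <- c(msg, "nSpecies must be >= 2")
  if (object@nYears < 2L) msg <- c(msg, "nYears must be >= 2")
  if (object@meanGrowth <= 0) msg <- c(msg, "meanGrowth must be > 0")
  if (object@baseAbundance <= 0) msg <- c(msg, "baseAbundance must be > 0")
  for (nm in c("sdInterspecific", "sdInterannual", "sdMeasurement"))
    if (slot(object, nm) < 0) msg <- c(msg, paste0(nm, " must be >= 0"))
  if (length(msg)) msg else TRUE
})

#' MCMC sampler configuration
#'
#' @slot nChains number of chains (>= 2, so that split-chain convergence
#'   diagnostics are defined).
#' @slot nDraws posterior draws kept per chain.
#' @slot nWarmup warmup (burn-in) iterations per chain, after adaptation.
#' @slot nAdapt sampler adaptation iterations.
#' @slot seed integer seed; chain c uses seed + c.
#' @slot rhatThreshold convergence bound on the potential scale reduction
#'   factor (default 1.05).
#' @export
setClass("McmcConfig", representation(
  nChains       = "integer",
  nDraws        = "integer",
  nWarmup       = "integer",
  nAdapt        = "integer",
  seed          = "integer",
  rhatThreshold = "numeric"
))

setValidity("McmcConfig", function(object) {
  msg <- character()
  if (object@nChains < 2L) msg <- c(msg, "nChains must be >= 2")
  if (object@nDraws < 1L) msg <- c(msg, "nDraws must be >= 1")
  if (object@rhatThreshold <= 1) msg <- c(msg, "rhatThreshold must be > 1")
  if (length(msg)) msg else TRUE
})

#' Fitted multi-species indicator
#'
#' Posterior draws from the hierarchical indicator model. \code{etaDraws} holds
#' the yearly indicator log growth rates \eqn{\eta_t} (growth from year
#' \eqn{t-1} into year \eqn{t}); column \code{t} of \code{etaDraws} is the
#' growth into \code{years[t + 1]}. \code{indicatorDraws} holds the indicator
#' \eqn{I_t = 100\exp(\sum_{u \le t} \eta_u)}, scaled to exactly 100 in the
#' base (first) year for every draw.
#'
#' @slot years the T consecutive years of the fitted dataset.
#' @slot etaDraws draws x (T-1) matrix of indicator log growth rates.
#' @slot sigmaGDraws draws of the species growth-deviation SD.
#' @slot indicatorDraws draws x T matrix of the indicator, base year = 100.
#' @slot nKnots number of spline knots used for the growth-rate smooth.
#' @slot diagnostics data.frame with one row per monitored parameter:
#'   \code{parameter}, \code{rhat}, \code{ess}.
#' @slot converged logical: all R-hat values at or below the threshold.
#' @slot mcmc the [McmcConfig()] used.
#' @slot meta list of fit metadata (observation model, parameterization, ...).
#' @export
setClass("IndicatorFit", representation(
  years          = "integer",
  etaDraws       = "matrix",
  sigmaGDraws    = "numeric",
  indicatorDraws = "matrix",
  nKnots         = "integer",
  diagnostics    = "data.frame",
  converged      = "logical",
  mcmc           = "McmcConfig",
  meta           = "list"
))

setValidity("IndicatorFit", function(object) {
  msg <- character()
  T <- length(object@years)
  if (ncol(object@etaDraws) != T - 1L)
    msg <- c(msg, "etaDraws must have T - 1 columns")
  if (ncol(object@indicatorDraws) != T)
    msg <- c(msg, "indicatorDraws must have T columns")
  if (nrow(object@indicatorDraws) &&
      any(object@indicatorDraws[, 1L] != 100))
    msg <- c(msg, "indicator base-year column must be identically 100")
  if (any(object@indicatorDraws <= 0))
    msg <- c(msg, "indicator draws must be positive")
  if (length(msg)) msg else TRUE
})

#' Result of the first-derivative test
#'
#' Per-year posterior probability that the indicator's log growth rate is at
#' or above zero. Assessable years are those with a defined growth rate, i.e.
#' all fitted years except the base year.
#'
#' @slot years assessable years.
#' @slot pGeq0 per-year probability in [0, 1] that \eqn{\eta_t \ge 0}.
#' @slot nDraws number of posterior draws used.
#' @slot fitMeta list: knots, seed, convergence flag.
#' @export
setClass("TestResult", representation(
  years   = "integer",
  pGeq0   = "numeric",
  nDraws  = "integer",
  fitMeta = "list"
))

setValidity("TestResult", function(object) {
  msg <- character()
  if (length(object@years) != length(object@pGeq0))
    msg <- c(msg, "years and pGeq0 must have the same length")
  if (any(object@pGeq0 < 0 | object@pGeq0 > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (is.null(object@fitMeta$converged))
    msg <- c(msg, "fitMeta must record convergence status")
  if (length(msg)) msg else TRUE
})

#' A replicated simulation scenario
#'
#' Bundles everything needed to replicate the calibration experiment: a
#' history (profile to generate, or an already-loaded dataset), simulation
#' parameters for the appended years, the smoothing levels to trial, the
#' number of runs, a master seed, and the known truth direction of the
#' simulated trend.
#'
#' @slot history a [HistoryProfile()] or a [SpeciesDataset()].
#' @slot sim [SimParams()] for the appended years.
#' @slot knotsList integer vector of indicator smoothing levels to trial.
#' @slot nRuns number of replicate runs (>= 1).
#' @slot masterSeed integer master seed; per-run seeds are derived from it.
#' @slot truthSign "positive" (growth multiplier >= 1, target truly met) or
#'   "negative" (multiplier < 1, decline truly continuing).
#' @slot presmoothFactor knots factor for species-level pre-smoothing.
#' @export
setClass("Scenario", representation(
  history         = "ANY",
  sim             = "SimParams",
  knotsList       = "integer",
  nRuns           = "integer",
  masterSeed      = "integer",
  truthSign       = "character",
  presmoothFactor = "numeric"
))

setValidity("Scenario", function(object) {
  msg <- character()
  if (!is(object@history, "HistoryProfile") && !is(object@history, "SpeciesDataset"))
    msg <- c(msg, "history must be a HistoryProfile or SpeciesDataset")
  if (object@nRuns < 1L) msg <- c(msg, "nRuns must be >= 1")
  if (!length(object@knotsList)) msg <- c(msg, "knotsList must be non-empty")
  if (!object@truthSign %in% c("positive", "negative"))
    msg <- c(msg, "truthSign must be 'positive' or 'negative'")
  sign_ok <- if (object@truthSign == "positive")
    object@sim@meanGrowth >= 1 else object@sim@meanGrowth < 1
  if (!sign_ok)
    msg <- c(msg, "truthSign is inconsistent with sim meanGrowth")
  if (length(msg)) msg else TRUE
})

#' Aggregated results of a scenario experiment
#'
#' @slot perRun long data.frame (run, knots, year, p) of per-run test results.
#' @slot finalYearP data.frame (run, knots, p) of final-year probabilities.
#' @slot meanPByYear data.frame (knots, year, meanP) averaged over runs.
#' @slot histogram named list (one entry per knots value) of 20 bin counts of
#'   final-year probabilities, in 5-percentage-point bins.
#' @slot failures data.frame (run, knots, reason) of excluded runs.
#' @slot scenario the [Scenario()] that produced the summary.
#' @export
setClass("ExperimentSummary", representation(
  perRun      = "data.frame",
  finalYearP  = "data.frame",
  meanPByYear = "data.frame",
  histogram   = "list",
  failures    = "data.frame",
  scenario    = "Scenario"
))

setValidity("ExperimentSummary", function(object) {
  msg <- character()
  if (nrow(object@meanPByYear) &&
      any(object@meanPByYear$meanP < 0 | object@meanPByYear$meanP > 1))
    msg <- c(msg, "mean probabilities must lie in [0, 1]")
  for (k in names(object@histogram)) {
    n_ok <- sum(object@finalYearP$p[object@finalYearP$knots == as.integer(k)] >= 0)
    if (sum(object@histogram[[k]]) != n_ok)
      msg <- c(msg, "histogram counts must sum to the number of successful runs")
  }
  if (length(msg)) msg else TRUE
})
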