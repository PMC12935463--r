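#' Construct a SpeciesDataset
#'
#' @param values numeric species x year matrix of positive abundance indices.
#'   Row names, if present, are used as species identifiers.
#' @param years integer vector of consecutive calendar years, one per column.
#' @param species optional character vector of unique species identifiers;
#'   defaults to the row names of \code{values} or \code{sp1, sp2, ...}.
#' @param se optional species x year matrix of log-scale standard errors.
#' @param provenance list recording how the dataset was produced.
#' @return A [SpeciesDataset-class] object.
#' @examples
#' ds <- speciesDataset(matrix(c(10, 20, 11, 22), 2), years = 2000:2001)
#' abundanceValues(ds)
#' @export
speciesDataset <- function(values, years, species = NULL, se = NULL,
                           provenance = list()) {
  values <- as.matrix(values)
  if (is.null(species))
    species <- rownames(values) %||% paste0("sp", seq_len(nrow(values)))
  years <- as.integer(years)
  if (length(years) != ncol(values))
    stop("length(years) must equal ncol(values)")
  dimnames(values) <- list(species, years)
  assays <- list(values = values)
  if (!is.null(se)) {
    se <- as.matrix(se)
    if (!identical(dim(se), dim(values)))
      stop("se must have the same dimensions as values")
    dimnames(se) <- dimnames(values)
    assays$se <- se
  }
  se_obj <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(year = years, row.names = as.character(years)),
    metadata = list(provenance = provenance)
  )
  methods::new("SpeciesDataset", se_obj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct simulation parameters
#'
#' @param meanGrowth per-annum multiplicative growth rate (> 0).
#' @param sdInterspecific,sdInterannual,sdMeasurement log-scale SDs (>= 0) of
#'   the three variability components; see [SimParams-class].
#' @param nYears number of simulated years.
#' @param seed integer RNG seed.
#' @return A [SimParams-class] object.
#' @examples
#' simParams(1.03, nYears = 8)
#' @export
simParams <- function(meanGrowth, sdInterspecific = 0, sdInterannual = 0,
                      sdMeasurement = 0, nYears = 8L, seed = 1L) {
  methods::new("SimParams",
    meanGrowth = as.numeric(meanGrowth),
    sdInterspecific = as.numeric(sdInterspecific),
    sdInterannual = as.numeric(sdInterannual),
    sdMeasurement = as.numeric(sdMeasurement),
    nYears = as.integer(nYears), seed = as.integer(seed))
}

#' Construct a history profile
#'
#' @param nSpecies,nYears dimensions of the synthetic history.
#' @param meanGrowth per-annum multiplier of the historical trend.
#' @param sdInterspecific,sdInterannual,sdMeasurement log-scale SDs.
#' @param baseAbundance starting index value for every species.
#' @param startYear first calendar year; defaults so the history ends in 2019.
#' @param label free-text tag.
#' @return A [HistoryProfile-class] object.
#' @export
historyProfile <- function(nSpecies, nYears, meanGrowth,
                           sdInterspecific = 0, sdInterannual = 0,
                           sdMeasurement = 0, baseAbundance = 100,
                           startYear = 2019L - as.integer(nYears) + 1L,
                           label = "custom") {
  methods::new("HistoryProfile",
    nSpecies = as.integer(nSpecies), nYears = as.integer(nYears),
    meanGrowth = as.numeric(meanGrowth),
    sdInterspecific = as.numeric(sdInterspecific),
    sdInterannual = as.numeric(sdInterannual),
    sdMeasurement = as.numeric(sdMeasurement),
    baseAbundance = as.numeric(baseAbundance),
    startYear = as.integer(startYear), label = label)
}

#' Preset history profiles
#'
#' Three synthetic stand-ins for the contrasting kinds of real multi-species
#' datasets the test is calibrated against: a low-variability 39-species
#' collection of long-run declining series ("bird-like"), an equally sized but
#' much noisier collection with large year-to-year fluctuations
#' ("lepidoptera-like"), and a larger, moderately variable multi-taxon
#' collection ("multi-taxa-like"). Variability values are package choices on
#' the log scale (see the methods vignette); all histories decline on average
#' and end in 2019.
#'
#' @param nYears length of the history in years (default 50, i.e. 1970-2019).
#' @return A [HistoryProfile-class].
#' @examples
#' birdLikeProfile()
#' @export
birdLikeProfile <- function(nYears = 50L) {
  historyProfile(39L, nYears, meanGrowth = 0.98,
                 sdInterspecific = 0.02, sdInterannual = 0.02,
                 sdMeasurement = 0.01, label = "bird-like")
}

#' @rdname birdLikeProfile
#' @export
lepidopteraLikeProfile <- function(nYears = 50L) {
  historyProfile(39L, nYears, meanGrowth = 0.98,
                 sdInterspecific = 0.05, sdInterannual = 0.20,
                 sdMeasurement = 0.05, label = "lepidoptera-like")
}

#' @rdname birdLikeProfile
#' @export
multiTaxaLikeProfile <- function(nYears = 50L) {
  historyProfile(300L, nYears, meanGrowth = 0.995,
                 sdInterspecific = 0.03, sdInterannual = 0.08,
                 sdMeasurement = 0.03, label = "multi-taxa-like")
}

#' Construct an MCMC configuration
#'
#' Defaults are production settings (4 chains of 1000 retained draws after
#' 1000 warmup); [shortMcmc()] gives a faster configuration suitable for
#' simulation experiments and tests.
#'
#' @param nChains,nDraws,nWarmup,nAdapt sampler sizes.
#' @param seed integer seed; chain c is seeded with seed + c.
#' @param rhatThreshold convergence bound for the flag on [fitIndicator()].
#' @return A [McmcConfig-class].
#' @export
mcmcConfig <- function(nChains = 4L, nDraws = 1000L, nWarmup = 1000L,
                       nAdapt = 500L, seed = 1L, rhatThreshold = 1.05) {
  methods::new("McmcConfig",
    nChains = as.integer(nChains), nDraws = as.integer(nDraws),
    nWarmup = as.integer(nWarmup), nAdapt = as.integer(nAdapt),
    seed = as.integer(seed), rhatThreshold = as.numeric(rhatThreshold))
}

#' @rdname mcmcConfig
#' @export
shortMcmc <- function(seed = 1L, rhatThreshold = 1.05) {
  mcmcConfig(nChains = 2L, nDraws = 500L, nWarmup = 1000L, nAdapt = 500L,
             seed = seed, rhatThreshold = rhatThreshold)
}

#' Construct a scenario
#'
#' @param history a [HistoryProfile-class] or [SpeciesDataset-class].
#' @param sim [SimParams-class] for the appended years.
#' @param knotsList integer vector of indicator smoothing levels to trial.
#' @param nRuns replicate count.
#' @param masterSeed integer master seed.
#' @param truthSign "positive" or "negative"; defaults from sim meanGrowth.
#' @param presmoothFactor knots factor for species-level pre-smoothing.
#' @return A [Scenario-class].
#' @export
scenario <- function(history, sim, knotsList = c(8L, 14L, 20L), nRuns = 50L,
                     masterSeed = 1L,
                     truthSign = if (sim@meanGrowth >= 1) "positive" else "negative",
                     presmoothFactor = 0.3) {
  methods::new("Scenario", history = history, sim = sim,
    knotsList = as.integer(knotsList), nRuns = as.integer(nRuns),
    masterSeed = as.integer(masterSeed), truthSign = truthSign,
    presmoothFactor = as.numeric(presmoothFactor))
}
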