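#' Derive a deterministic per-species substream seed
#'
#' One master seed expands to independent per-species substreams, so that
#' adding species to a simulation does not perturb the series already drawn.
#' Each substream seeds R's Mersenne-Twister generator. Kept below 2^31 - 1.
#' @noRd
substreamSeed <- function(seed, i) {
  # arithmetic in doubles (exact below 2^53), coerced only after the modulo
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + i * 96043) %% 2147483647)
}

#' Simulate species abundance series with known growth and variability
#'
#' Generates a [SpeciesDataset-class] under the generative model of
#' [SimParams-class]: for species \eqn{i}, a constant log-scale deviation
#' \eqn{a_i \sim N(0, \sigma_{is}^2)}; for each year step, an independent
#' deviation \eqn{b_{it} \sim N(0, \sigma_{ia}^2)}; latent log abundance
#' \eqn{x_{it} = x_{i,t-1} + \ln g + a_i + b_{it}} started at
#' \eqn{x_{i1} = \ln(\mathrm{base}_i)}; observed value
#' \eqn{\exp(x_{it} + e_{it})} with \eqn{e_{it} \sim N(0, \sigma_{me}^2)}.
#' Measurement noise applies to every year, including the first, and is never
#' propagated into the latent walk.
#'
#' With all SDs zero the output is exactly \eqn{\mathrm{base}_i \, g^{t-1}}.
#' Randomness uses R's Mersenne-Twister with one substream per species derived
#' from \code{params@seed}, so results are reproducible and adding species
#' leaves existing series unchanged.
#'
#' @param params a [SimParams-class].
#' @param nSpecies number of species (>= 1).
#' @param startYear calendar year of the first simulated value.
#' @param baseValues positive numeric of length nSpecies (or 1, recycled):
#'   abundance in the first simulated year.
#' @return A [SpeciesDataset-class] of nSpecies x params@nYears.
#' @examples
#' ds <- simulateGrowthSeries(simParams(1.03, nYears = 8), nSpecies = 3,
#'                            startYear = 2020, baseValues = 100)
#' abundanceValues(ds)[1, ]  # 100 * 1.03^(0:7)
#' @export
simulateGrowthSeries <- function(params, nSpecies, startYear = 2020L,
                                 baseValues = 100) {
  stopifnot(is(params, "SimParams"))
  methods::validObject(params)
  nSpecies <- as.integer(nSpecies)
  if (nSpecies < 1L) stop("nSpecies must be >= 1")
  baseValues <- rep_len(as.numeric(baseValues), nSpecies)
  bad <- which(!is.finite(baseValues) | baseValues <= 0)
  if (length(bad))
    stop("non-positive base value for species ", paste0("sp", bad[1L]))
  Tn <- params@nYears
  vals <- matrix(NA_real_, nSpecies, Tn)
  lg <- log(params@meanGrowth)
  for (i in seq_len(nSpecies)) {
    set.seed(substreamSeed(params@seed, i))
    a_i <- rnorm(1L, 0, params@sdInterspecific)
    b_it <- rnorm(max(Tn - 1L, 0L), 0, params@sdInterannual)
    e_it <- rnorm(Tn, 0, params@sdMeasurement)
    x <- cumsum(c(log(baseValues[i]), rep(lg + a_i, Tn - 1L) + b_it))
    vals[i, ] <- exp(x + e_it)
  }
  speciesDataset(vals, years = startYear + seq_len(Tn) - 1L,
                 provenance = list(generator = "simulateGrowthSeries",
                                   params = params, nSpecies = nSpecies))
}

#' Generate a synthetic multi-decade history
#'
#' Builds a synthetic historical dataset from a [HistoryProfile-class]: a set
#' of species index series with a common (typically declining) trend and the
#' profile's variability structure, standing in for real long-term monitoring
#' data. All series start at \code{baseAbundance}.
#'
#' @param profile a [HistoryProfile-class].
#' @param seed integer RNG seed.
#' @return A [SpeciesDataset-class] of profile@nSpecies x profile@nYears.
#' @examples
#' h <- generateHistory(birdLikeProfile(nYears = 30), seed = 1)
#' @export
generateHistory <- function(profile, seed = 1L) {
  stopifnot(is(profile, "HistoryProfile"))
  methods::validObject(profile)
  if (profile@nSpecies < 2L) stop("a history needs at least 2 species")
  params <- simParams(profile@meanGrowth, profile@sdInterspecific,
                      profile@sdInterannual, profile@sdMeasurement,
                      nYears = profile@nYears, seed = seed)
  ds <- simulateGrowthSeries(params, profile@nSpecies,
                             startYear = profile@startYear,
                             baseValues = profile@baseAbundance)
  S4Vectors::metadata(ds)$provenance <-
    list(generator = "generateHistory", profile = profile, seed = seed)
  ds
}

#' Append simulated future years to a history
#'
#' Simulates \code{params@nYears} new years for every species in the history
#' and joins them to the historical series, matching abundances in the join
#' (final historical) year: the simulated series is rescaled so that its
#' year-0 value equals the species' final historical value, and that year-0
#' point is then discarded, so measurement error of the join-year observation
#' is not double-counted. Historical values are returned unchanged.
#'
#' @param history a [SpeciesDataset-class].
#' @param params a [SimParams-class] for the appended years.
#' @param seed integer seed; defaults to \code{params@seed}.
#' @return A [SpeciesDataset-class] spanning the historical years plus
#'   \code{params@nYears} new consecutive years.
#' @examples
#' h <- generateHistory(birdLikeProfile(nYears = 20), seed = 1)
#' full <- appendSimulated(h, simParams(1.03, nYears = 8), seed = 2)
#' range(datasetYears(full))
#' @export
appendSimulated <- function(history, params, seed = params@seed) {
  stopifnot(is(history, "SpeciesDataset"), is(params, "SimParams"))
  if (params@nYears < 1L) stop("params@nYears must be >= 1")
  hv <- abundanceValues(history)
  last <- hv[, ncol(hv)]
  simp <- simParams(params@meanGrowth, params@sdInterspecific,
                    params@sdInterannual, params@sdMeasurement,
                    nYears = params@nYears + 1L, seed = seed)
  sim <- simulateGrowthSeries(simp, nSpecies = nrow(hv),
                              startYear = max(datasetYears(history)),
                              baseValues = last)
  sv <- abundanceValues(sim)
  if (nrow(sv) != nrow(hv))
    stop("species mismatch between history and simulated block")
  # rescale so simulated year 0 matches the join-year observation, then drop it
  scaled <- sv * (last / sv[, 1L])
  newv <- cbind(hv, scaled[, -1L, drop = FALSE])
  yrs <- c(datasetYears(history),
           max(datasetYears(history)) + seq_len(params@nYears))
  speciesDataset(newv, years = yrs, species = speciesIds(history),
                 provenance = list(generator = "appendSimulated",
                                   history = provenance(history),
                                   params = params, seed = seed))
}

#' Estimate variability components from a dataset
#'
#' Decomposes observed annual log growth rates \eqn{d_{it} = \ln v_{it} -
#' \ln v_{i,t-1}} into the components of the generative model: the mean
#' growth multiplier is \eqn{\exp(\bar d)}; the interspecific SD is the SD
#' across species of each species' mean annual log growth; the interannual SD
#' is the pooled within-species SD of the detrended growth rates
#' \eqn{d_{it} - \bar d_i}; the measurement SD is the mean of the supplied
#' log-scale SE matrix, or 0 when absent. Estimates are approximately
#' unbiased when measurement error is small relative to interannual
#' variation; both year-level components otherwise fold some measurement
#' noise into the interannual term.
#'
#' @param dataset a [SpeciesDataset-class] with >= 2 species and >= 3 years.
#' @return A list with elements \code{meanGrowth}, \code{sdInterspecific},
#'   \code{sdInterannual}, \code{sdMeasurement}.
#' @examples
#' ds <- simulateGrowthSeries(simParams(1.03, nYears = 10), 5, baseValues = 100)
#' estimateVariability(ds)
#' @export
estimateVariability <- function(dataset) {
  stopifnot(is(dataset, "SpeciesDataset"))
  if (nrow(dataset) < 2L) stop("need at least 2 species")
  if (ncol(dataset) < 3L) stop("need at least 3 years")
  v <- abundanceValues(dataset)
  if (any(v <= 0)) stop("all abundance values must be positive")
  d <- t(diff(t(log(v))))              # species x (T-1) annual log growth
  sp_mean <- rowMeans(d)
  resid <- d - sp_mean
  pooled_var <- sum(resid^2) / (nrow(d) * (ncol(d) - 1L))
  se <- seValues(dataset)
  list(meanGrowth = exp(mean(d)),
       sdInterspecific = sd(sp_mean),
       sdInterannual = sqrt(pooled_var),
       sdMeasurement = if (is.null(se)) 0 else mean(se))
}
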