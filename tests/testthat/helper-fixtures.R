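# Shared fixtures, computed once per test session and cached. Everything is
# generated in code; MCMC-backed fixtures use fixed seeds and the short
# sampler configuration.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Noise-free common-growth dataset (10 species, 15 years, +3%/yr) and its fit.
fxNoiseFreeData <- function() fixture("nfData",
  simulateGrowthSeries(simParams(1.03, nYears = 15, seed = 11), nSpecies = 10,
                       startYear = 2000, baseValues = 100))

fxNoiseFreeFit <- function() fixture("nfFit",
  fitIndicator(fxNoiseFreeData(), nKnots = 5, mcmc = shortMcmc(seed = 21)))

# Realistic noisy pipeline fixture: 20-year declining bird-like history with
# 8 appended +3% years, pre-smoothed, fitted at 8 knots.
fxNoisySmoothed <- function() fixture("noisySmoothed", {
  h <- generateHistory(birdLikeProfile(nYears = 20), seed = 31)
  full <- appendSimulated(h, simParams(1.03, 0.02, 0.02, 0.01, nYears = 8),
                          seed = 32)
  presmoothDataset(full)
})

fxNoisyFit <- function() fixture("noisyFit",
  fitIndicator(fxNoisySmoothed(), nKnots = 8, mcmc = shortMcmc(seed = 41)))

# Hand-constructed IndicatorFit from a given eta draw matrix (bypasses MCMC;
# used to test the draw-counting test statistic and decision rule exactly).
manualFit <- function(etaDraws, years = seq_len(ncol(etaDraws) + 1L) + 2019L,
                      converged = TRUE) {
  cs <- if (ncol(etaDraws) == 1L) etaDraws else t(apply(etaDraws, 1L, cumsum))
  lnI <- cbind(0, cs)
  ind <- 100 * exp(lnI)
  ind[, 1L] <- 100
  colnames(ind) <- as.character(years)
  colnames(etaDraws) <- as.character(years[-1L])
  methods::new("IndicatorFit",
    years = as.integer(years), etaDraws = etaDraws,
    sigmaGDraws = rep(0.01, nrow(etaDraws)), indicatorDraws = ind,
    nKnots = 3L,
    diagnostics = data.frame(parameter = "eta[1]", rhat = 1, ess = 1000),
    converged = converged, mcmc = shortMcmc(), meta = list(manual = TRUE))
}

# Tiny scenario used by experiment and reproducibility tests: a lightly
# noisy history with a zero-variance +3% simulated trend appended.
fxTinyScenario <- function(masterSeed = 71L) scenario(
  historyProfile(10, 15, 0.99, 0.01, 0.02, 0.01, label = "tiny"),
  simParams(1.03, nYears = 5), knotsList = 5L, nRuns = 2L,
  masterSeed = masterSeed)

fxTinySummary <- function() fixture("tinySummary",
  runScenario(fxTinyScenario(), mcmc = shortMcmc(seed = 51)))
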