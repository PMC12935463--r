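test_that("zero-variance simulation is exact geometric growth", {
  ds <- simulateGrowthSeries(simParams(1.03, nYears = 8), nSpecies = 3,
                             startYear = 2020, baseValues = 100)
  expected <- 100 * 1.03^(0:7)
  for (i in 1:3)
    expect_equal(unname(abundanceValues(ds)[i, ]), expected, tolerance = 1e-14)
  expect_identical(datasetYears(ds), 2020:2027)
})

test_that("simulation is reproducible and species substreams are stable", {
  p <- simParams(1.01, 0.05, 0.1, 0.02, nYears = 10, seed = 42)
  a <- simulateGrowthSeries(p, 5, baseValues = 50)
  b <- simulateGrowthSeries(p, 5, baseValues = 50)
  expect_identical(abundanceValues(a), abundanceValues(b))
  # adding species must not perturb the series already drawn
  c7 <- simulateGrowthSeries(p, 7, baseValues = 50)
  expect_identical(abundanceValues(c7)[1:5, ], abundanceValues(a))
})

test_that("sample moments of simulated growth match the generative model", {
  # interspecific only: each species' mean annual log growth is ln(1) + a_i,
  # so the across-species mean is within 3 Monte-Carlo SEs of zero
  p <- simParams(1.0, sdInterspecific = 0.1, nYears = 8, seed = 7)
  ds <- simulateGrowthSeries(p, 1000, baseValues = 100)
  d <- t(diff(t(log(abundanceValues(ds)))))
  spMean <- rowMeans(d)
  expect_lt(abs(mean(spMean)), 3 * 0.1 / sqrt(1000))
  expect_lt(abs(sd(spMean) - 0.1), 3 * 0.1 / sqrt(2 * 999))
  # interannual only: pooled mean log growth centred on ln g
  p2 <- simParams(1.02, sdInterannual = 0.08, nYears = 8, seed = 8)
  ds2 <- simulateGrowthSeries(p2, 1000, baseValues = 100)
  d2 <- t(diff(t(log(abundanceValues(ds2)))))
  expect_lt(abs(mean(d2) - log(1.02)), 3 * 0.08 / sqrt(length(d2)))
})

test_that("invalid simulation inputs are rejected with clear messages", {
  expect_error(simulateGrowthSeries(simParams(1.03), 2, baseValues = c(10, -1)),
               "sp2")
  expect_error(simParams(1.03, sdInterspecific = -0.1), "non-negative")
  expect_error(simParams(-1), "positive")
  expect_error(simParams(1.03, nYears = 0), "nYears")
})

test_that("generateHistory produces declining series for multiplier < 1", {
  h <- generateHistory(birdLikeProfile(nYears = 50), seed = 3)
  expect_equal(dim(abundanceValues(h)), c(39L, 50L))
  meanLog <- colMeans(log(abundanceValues(h)))
  slope <- coef(lm(meanLog ~ seq_along(meanLog)))[2]
  expect_lt(slope, 0)
})

test_that("degenerate histories are constant or rejected", {
  prof <- historyProfile(3, 10, meanGrowth = 1.0, baseAbundance = 77)
  h <- generateHistory(prof, seed = 1)
  expect_equal(abundanceValues(h), matrix(77, 3, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(historyProfile(1, 10, 0.98), "nSpecies")
})

test_that("high-interannual profiles yield noisier growth than low ones", {
  withinSD <- function(profile, seed) {
    d <- t(diff(t(log(abundanceValues(generateHistory(profile, seed))))))
    mean(apply(d, 1L, sd))
  }
  seeds <- 1:20
  birdSD <- vapply(seeds, function(s) withinSD(birdLikeProfile(nYears = 20), s),
                   numeric(1))
  lepSD <- vapply(seeds, function(s)
    withinSD(lepidopteraLikeProfile(nYears = 20), s), numeric(1))
  expect_true(all(lepSD > birdSD))
})

test_that("appendSimulated matches abundances at the join year", {
  h <- generateHistory(historyProfile(3, 10, 0.99, 0.01, 0.02, 0.01), seed = 5)
  # zero-variance appended block continues exactly from the final value
  full <- appendSimulated(h, simParams(1.01, nYears = 4), seed = 6)
  last <- abundanceValues(h)[, 10]
  for (k in 1:4)
    expect_equal(unname(abundanceValues(full)[, 10 + k]),
                 unname(last * 1.01^k), tolerance = 1e-14)
  # historical block is bit-identical and years extend consecutively
  expect_identical(abundanceValues(full)[, 1:10], abundanceValues(h))
  expect_identical(datasetYears(full),
                   c(datasetYears(h), max(datasetYears(h)) + 1:4))
})

test_that("appended years run 2020-2027 for a 1970-2019 history", {
  h <- generateHistory(historyProfile(2, 50, 0.99, startYear = 1970), seed = 1)
  full <- appendSimulated(h, simParams(1.03, 0.01, 0.02, 0.01, nYears = 8),
                          seed = 2)
  expect_identical(range(datasetYears(full)), c(1970L, 2027L))
})

test_that("join-year continuity is exact when measurement error is zero", {
  h <- generateHistory(historyProfile(4, 8, 0.98), seed = 9)
  params <- simParams(1.02, sdInterspecific = 0.05, sdInterannual = 0.1,
                      sdMeasurement = 0, nYears = 3)
  full <- appendSimulated(h, params, seed = 10)
  # with no measurement noise the simulated year-0 equals the join value, so
  # the rescaling is the identity: re-simulating reproduces the appended block
  sim <- simulateGrowthSeries(
    simParams(1.02, 0.05, 0.1, 0, nYears = 4, seed = 10), 4,
    startYear = max(datasetYears(h)),
    baseValues = abundanceValues(h)[, 8])
  expect_equal(abundanceValues(full)[, 9:11],
               abundanceValues(sim)[, 2:4, drop = FALSE],
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("estimateVariability recovers known components", {
  # zero-variance dataset: exact multiplier, zero SDs
  ds <- simulateGrowthSeries(simParams(1.03, nYears = 10), 5, baseValues = 100)
  est <- estimateVariability(ds)
  expect_equal(est$meanGrowth, 1.03, tolerance = 1e-12)
  expect_equal(est$sdInterspecific, 0, tolerance = 1e-12)
  expect_equal(est$sdInterannual, 0, tolerance = 1e-12)
  expect_identical(est$sdMeasurement, 0)
  # interspecific-only recovery within 20%
  ds2 <- simulateGrowthSeries(
    simParams(1.0, sdInterspecific = 0.05, nYears = 30, seed = 12), 500,
    baseValues = 100)
  est2 <- estimateVariability(ds2)
  expect_lt(abs(est2$sdInterspecific - 0.05) / 0.05, 0.2)
  # interannual-only recovery within 20%
  ds3 <- simulateGrowthSeries(
    simParams(1.0, sdInterannual = 0.1, nYears = 30, seed = 13), 200,
    baseValues = 100)
  est3 <- estimateVariability(ds3)
  expect_lt(abs(est3$sdInterannual - 0.1) / 0.1, 0.2)
})

test_that("estimateVariability enforces its preconditions", {
  one <- speciesDataset(matrix(1:5 * 1.0, 1), years = 2000:2004)
  expect_error(estimateVariability(one), "2 species")
  two <- speciesDataset(matrix(c(1, 2, 1, 2), 2), years = 2000:2001)
  expect_error(estimateVariability(two), "3 years")
})

test_that("SpeciesDataset validity rejects malformed inputs", {
  expect_error(speciesDataset(matrix(c(1, -2, 3, 4), 2), years = 2000:2001),
               "> 0")
  expect_error(speciesDataset(matrix(1:4 * 1.0, 2), years = c(2000L, 2002L)),
               "consecutive")
  expect_error(speciesDataset(matrix(1:4 * 1.0, 2), years = 2000:2001,
                              se = matrix(-1, 2, 2)), ">= 0")
})
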