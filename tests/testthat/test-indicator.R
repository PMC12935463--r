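test_that("the growth-rate spline basis has the promised shape and rank", {
  B <- buildSplineBasis(2000:2009, 3)
  expect_identical(dim(B), c(9L, 5L))
  expect_identical(qr(B)$rank, 5L)
  # constant growth is representable exactly through the intercept column
  expect_true(all(B[, "intercept"] == 1))
  # more knots strictly enlarge the column space on the same years
  B2 <- buildSplineBasis(2000:2009, 5)
  expect_gt(qr(cbind(B, B2))$rank, qr(B)$rank)
  # rank deficiency (too many knots for the span) is an error
  expect_error(buildSplineBasis(2000:2009, 9), "rank deficient")
  expect_error(buildSplineBasis(2000:2009, 1), "nKnots")
})

test_that("geometric-mean index matches its closed form", {
  ds <- speciesDataset(rbind(c(1, 4), c(1, 9)), years = 2000:2001)
  expect_equal(unname(geometricMeanIndex(ds)), c(100, 600))
  const <- speciesDataset(matrix(5, 3, 4), years = 2000:2003)
  expect_equal(unname(geometricMeanIndex(const)), rep(100, 4))
  one <- speciesDataset(matrix(c(2, 3, 5), 1), years = 2000:2002)
  expect_equal(unname(geometricMeanIndex(one)), 100 * c(2, 3, 5) / 2)
})

test_that("noise-free common growth is recovered by the posterior", {
  fit <- fxNoiseFreeFit()
  expect_true(isConverged(fit))
  expect_lt(max(abs(colMeans(etaDraws(fit)) - log(1.03))), 0.005)
})

test_that("the indicator is exactly 100 in the base year for every draw", {
  fit <- fxNoiseFreeFit()
  expect_true(all(indicatorDraws(fit)[, 1] == 100))
  expect_true(all(indicatorDraws(fxNoisyFit())[, 1] == 100))
})

test_that("log indicator change equals the summed growth rates per draw", {
  for (fit in list(fxNoiseFreeFit(), fxNoisyFit())) {
    lhs <- log(indicatorDraws(fit)[, ncol(indicatorDraws(fit))]) - log(100)
    rhs <- rowSums(etaDraws(fit))
    expect_equal(lhs, rhs, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("posterior-mean indicator agrees with the geometric-mean oracle", {
  # low-noise two-species toy set: the model's indicator should track the
  # deterministic geometric-mean index within posterior uncertainty
  ds <- simulateGrowthSeries(simParams(1.02, sdInterannual = 0.01,
                                       nYears = 12, seed = 14),
                             2, baseValues = c(80, 120))
  fit <- fitIndicator(ds, nKnots = 4, mcmc = shortMcmc(seed = 15))
  lnI <- log(indicatorDraws(fit))
  lnG <- log(geometricMeanIndex(ds))
  postSD <- apply(lnI, 2, sd)
  dev <- abs(colMeans(lnI) - lnG)
  expect_true(all(dev[-1] <= pmax(2 * postSD[-1], 0.02)))
})

test_that("credible intervals are symmetric-tail quantiles of the draws", {
  fit <- fxNoisyFit()
  s <- indicatorSummary(fit, credibleMass = 0.95)
  i <- 3
  draws <- indicatorDraws(fit)[, i]
  expect_equal(s$indicator$lower[i], unname(quantile(draws, 0.025)))
  expect_equal(s$indicator$upper[i], unname(quantile(draws, 0.975)))
  expect_true(all(s$indicator$upper >= s$indicator$lower))
  expect_true(all(s$eta$upper >= s$eta$lower))
  expect_error(indicatorSummary(fit, 1.2), "credibleMass")
})

test_that("noise-free growth-rate intervals are tight in interior years", {
  s <- indicatorSummary(fxNoiseFreeFit(), 0.95)
  interior <- 2:(nrow(s$eta) - 1)
  expect_true(all((s$eta$upper - s$eta$lower)[interior] < 0.01))
})

test_that("final-year growth uncertainty exceeds the interior on noisy data", {
  s <- indicatorSummary(fxNoisyFit(), 0.95)
  w <- s$eta$upper - s$eta$lower
  expect_gt(w[length(w)], median(w[2:(length(w) - 1)]))
})

test_that("indicator fit inputs are validated", {
  one <- speciesDataset(matrix(1:5 * 1.0, 1), years = 2000:2004)
  expect_error(fitIndicator(one, 3), "2 species")
  ds <- fxNoiseFreeData()
  expect_error(fitIndicator(ds, 3, obsModel = "se"), "se")
})
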