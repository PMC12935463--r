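# Build a minimal ExperimentSummary around a given final-year probability
# vector, bypassing MCMC (for exact tests of the aggregation contracts).
summaryFromFinalP <- function(p, truthSign, knots = 8L, finalYear = 2027L) {
  g <- if (truthSign == "positive") 1.03 else 0.99
  scn <- scenario(historyProfile(5, 10, 0.99), simParams(g, nYears = 8),
                  knotsList = knots, nRuns = length(p), masterSeed = 1L,
                  truthSign = truthSign)
  perRun <- data.frame(run = seq_along(p), knots = knots, year = finalYear,
                       p = p)
  meanP <- data.frame(knots = knots, year = finalYear, meanP = mean(p))
  methods::new("ExperimentSummary",
    perRun = perRun,
    finalYearP = perRun[, c("run", "knots", "p")],
    meanPByYear = meanP,
    histogram = setNames(list(finalYearHistogram(p)), knots),
    failures = data.frame(run = integer(), knots = integer(),
                          reason = character()),
    scenario = scn)
}

test_that("final-year histograms use half-open 5-point bins, last closed", {
  h <- finalYearHistogram(c(0.02, 0.03, 0.99))
  expect_identical(length(h), 20L)
  expect_identical(unname(h[1]), 2L)
  expect_identical(unname(h[20]), 1L)
  # exact 1.0 falls in the closed last bin; boundaries open the next bin
  h2 <- finalYearHistogram(c(1.0, 0.05, 0.95, 0))
  expect_identical(unname(h2[20]), 2L)  # 1.0 and 0.95
  expect_identical(unname(h2[2]), 1L)   # 0.05
  expect_identical(unname(h2[1]), 1L)   # 0
  # counts sum to the number of inputs
  set.seed(23)
  p <- runif(50)
  expect_identical(sum(finalYearHistogram(p)), 50L)
  expect_error(finalYearHistogram(c(0.5, 1.2)), "0, 1")
})

test_that("error rates are computed and monotone over the threshold grid", {
  pos <- summaryFromFinalP(rep(0.99, 10), "positive")
  neg <- summaryFromFinalP(c(0.01, 0.2, 0.96, 0.5, 0.02), "negative")
  tab <- errorRateTable(pos, neg, thresholds = c(0.5, 0.95, 0.99))
  expect_identical(tab$fnr[tab$threshold == 0.95], 0)
  expect_identical(tab$fpr[tab$threshold == 0.95], 1 / 5)
  # towards theta = 1: FNR rises to 1 (no exact ties at 1), FPR falls to 0
  set.seed(29)
  pos2 <- summaryFromFinalP(runif(40, 0.2, 0.999), "positive")
  neg2 <- summaryFromFinalP(runif(40, 0.001, 0.8), "negative")
  grid <- seq(0.05, 0.999, by = 0.01)
  tab2 <- errorRateTable(pos2, neg2, thresholds = grid)
  expect_true(all(diff(tab2$fnr) >= 0))
  expect_true(all(diff(tab2$fpr) <= 0))
  expect_identical(tab2$fnr[nrow(tab2)], 1)
  expect_identical(tab2$fpr[nrow(tab2)], 0)
})

test_that("mismatched scenario pairs are rejected", {
  pos <- summaryFromFinalP(rep(0.9, 5), "positive")
  neg <- summaryFromFinalP(rep(0.1, 5), "negative", knots = 14L)
  expect_error(errorRateTable(pos, neg), "smoothing levels")
  neg2 <- summaryFromFinalP(rep(0.1, 5), "negative", finalYear = 2030L)
  expect_error(errorRateTable(pos, neg2), "different years")
  expect_error(errorRateTable(neg2, pos), "truthSign")
})

test_that("scenario truth-sign consistency is enforced", {
  expect_error(
    scenario(historyProfile(5, 10, 0.99), simParams(0.99, nYears = 8),
             truthSign = "positive"),
    "inconsistent")
})

test_that("a zero-variance increasing scenario finds high final-year p", {
  res <- fxTinySummary()
  expect_identical(nrow(res@failures), 0L)
  expect_identical(sort(unique(res@perRun$run)), 1:2)
  expect_true(all(res@finalYearP$p > 0.9))
  fy <- max(res@perRun$year)
  expect_equal(res@meanPByYear$meanP[res@meanPByYear$year == fy],
               mean(res@finalYearP$p))
  # aggregates are exact functions of the per-run table
  recomputed <- aggregate(p ~ knots + year, data = res@perRun, FUN = mean)
  expect_equal(recomputed$p, res@meanPByYear$meanP)
  expect_identical(sum(res@histogram[["5"]]), nrow(res@finalYearP))
})

test_that("identical master seeds reproduce the experiment bit-for-bit", {
  res1 <- fxTinySummary()
  res2 <- runScenario(fxTinyScenario(), mcmc = shortMcmc(seed = 51))
  expect_identical(res1@perRun, res2@perRun)
  expect_identical(res1@histogram, res2@histogram)
  d1 <- file.path(tempdir(), "repro1"); d2 <- file.path(tempdir(), "repro2")
  writeExperimentSummary(res1, d1)
  writeExperimentSummary(res2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
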