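#' Accessors for SpeciesDataset
#'
#' @param x a [SpeciesDataset-class].
#' @return \code{abundanceValues}: the species x year value matrix;
#'   \code{seValues}: the SE matrix or NULL; \code{datasetYears}: integer
#'   years; \code{speciesIds}: character identifiers; \code{nSpecies} /
#'   \code{nYears}: dimensions; \code{provenance}: the provenance list.
#' @examples
#' ds <- speciesDataset(matrix(1:4 * 1.0, 2), years = 2000:2001)
#' datasetYears(ds)
#' nSpecies(ds)
#' @export
abundanceValues <- function(x) SummarizedExperiment::assay(x, "values")

#' @rdname abundanceValues
#' @export
seValues <- function(x) {
  if ("se" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "se") else NULL
}

#' @rdname abundanceValues
#' @export
datasetYears <- function(x) as.integer(SummarizedExperiment::colData(x)$year)

#' @rdname abundanceValues
#' @export
speciesIds <- function(x) rownames(x)

#' @rdname abundanceValues
#' @export
nSpecies <- function(x) nrow(x)

#' @rdname abundanceValues
#' @export
nYears <- function(x) ncol(x)

#' @rdname abundanceValues
#' @export
provenance <- function(x) S4Vectors::metadata(x)$provenance

#' Restrict a dataset to a span of years
#'
#' @param x a [SpeciesDataset-class].
#' @param from,to first and last year to keep (defaults: no restriction).
#' @return A [SpeciesDataset-class] covering the requested years.
#' @export
windowYears <- function(x, from = min(datasetYears(x)), to = max(datasetYears(x))) {
  yr <- datasetYears(x)
  keep <- yr >= from & yr <= to
  if (!any(keep)) stop("no years in the requested window")
  speciesDataset(abundanceValues(x)[, keep, drop = FALSE], yr[keep],
                 species = speciesIds(x),
                 se = if (!is.null(seValues(x))) seValues(x)[, keep, drop = FALSE],
                 provenance = c(provenance(x), list(window = c(from, to))))
}

#' Accessors for IndicatorFit
#'
#' @param x an [IndicatorFit-class].
#' @return \code{etaDraws}: draws x (T-1) matrix of yearly log growth rates
#'   (column t is the growth into \code{fitYears(x)[t + 1]});
#'   \code{indicatorDraws}: draws x T indicator matrix (base year = 100);
#'   \code{fitYears}: the fitted years; \code{isConverged}: convergence flag;
#'   \code{fitDiagnostics}: per-parameter R-hat and effective sample size.
#' @export
etaDraws <- function(x) x@etaDraws

#' @rdname etaDraws
#' @export
indicatorDraws <- function(x) x@indicatorDraws

#' @rdname etaDraws
#' @export
fitYears <- function(x) x@years

#' @rdname etaDraws
#' @export
isConverged <- function(x) x@converged

#' @rdname etaDraws
#' @export
fitDiagnostics <- function(x) x@diagnostics

#' Accessors for TestResult
#'
#' @param x a [TestResult-class].
#' @return \code{pGeq0}: named per-year probabilities that the indicator's
#'   log growth rate is >= 0; \code{testYears}: the assessable years.
#' @export
pGeq0 <- function(x) setNames(x@pGeq0, x@years)

#' @rdname pGeq0
#' @export
testYears <- function(x) x@years

setMethod("show", "SpeciesDataset", function(object) {
  yr <- datasetYears(object)
  cat("SpeciesDataset:", nrow(object), "species x", ncol(object), "years (",
      min(yr), "-", max(yr), ")\n")
  if ("se" %in% SummarizedExperiment::assayNames(object))
    cat("  with log-scale standard errors\n")
  pr <- provenance(object)
  if (length(pr)) cat("  provenance:", paste(names(pr), collapse = ", "), "\n")
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: growth %.4g/yr over %d years; SDs interspecific %.3g, interannual %.3g, measurement %.3g; seed %d\n",
    object@meanGrowth, object@nYears, object@sdInterspecific,
    object@sdInterannual, object@sdMeasurement, object@seed))
})

setMethod("show", "HistoryProfile", function(object) {
  cat(sprintf(
    "HistoryProfile '%s': %d species x %d years from %d, growth %.4g/yr\n",
    object@label, object@nSpecies, object@nYears, object@startYear,
    object@meanGrowth))
})

setMethod("show", "IndicatorFit", function(object) {
  yr <- object@years
  cat(sprintf(
    "IndicatorFit: %d years (%d-%d), %d knots, %d draws, %s\n",
    length(yr), min(yr), max(yr), object@nKnots, nrow(object@etaDraws),
    if (object@converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("  max R-hat %.3f, min ESS %.0f\n",
              max(object@diagnostics$rhat, na.rm = TRUE),
              min(object@diagnostics$ess, na.rm = TRUE)))
})

setMethod("show", "TestResult", function(object) {
  cat("TestResult over", length(object@years), "years;",
      "final year", max(object@years),
      sprintf("P(growth >= 0) = %.3f\n", object@pGeq0[which.max(object@years)]))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario: %s truth, %d runs, knots {%s}, master seed %d\n",
              object@truthSign, object@nRuns,
              paste(object@knotsList, collapse = ", "), object@masterSeed))
})

setMethod("show", "ExperimentSummary", function(object) {
  cat("ExperimentSummary:", length(unique(object@perRun$run)), "runs,",
      "knots {", paste(unique(object@perRun$knots), collapse = ", "), "}\n")
  if (nrow(object@failures))
    cat("  ", nrow(object@failures), "run-level failures excluded\n")
})
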