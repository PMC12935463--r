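#' Read a species x year abundance table from CSV
#'
#' Long format has columns \code{species, year, value} and optionally
#' \code{se}; wide format has a first column of species identifiers and one
#' column per year, named by the year. Validation rejects missing columns,
#' non-numeric or non-positive values, duplicate species-year pairs (named by
#' row) and gaps in the year sequence.
#'
#' @param path CSV file path.
#' @param format "long" or "wide".
#' @return A [SpeciesDataset-class].
#' @export
readSpeciesDataset <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "long") {
    need <- c("species", "year", "value")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "))
    if (!is.numeric(df$year) || !is.numeric(df$value))
      stop("'year' and 'value' must be numeric")
    dup <- duplicated(df[c("species", "year")])
    if (any(dup)) {
      i <- which(dup)[1L]
      stop(sprintf("duplicate (species, year) pair '%s', %d at row %d",
                   df$species[i], df$year[i], i))
    }
    years <- sort(unique(as.integer(df$year)))
    if (length(years) > 1L && any(diff(years) != 1L))
      stop("year sequence has gaps: ", paste(years, collapse = ", "))
    species <- unique(df$species)
    v <- matrix(NA_real_, length(species), length(years),
                dimnames = list(species, years))
    v[cbind(match(df$species, species), match(df$year, years))] <- df$value
    if (anyNA(v))
      stop("incomplete species x year grid (every species needs every year)")
    se <- NULL
    if ("se" %in% names(df)) {
      se <- matrix(NA_real_, length(species), length(years))
      se[cbind(match(df$species, species), match(df$year, years))] <- df$se
    }
    speciesDataset(v, years, species = species, se = se,
                   provenance = list(path = path, format = "long"))
  } else {
    if (ncol(df) < 3L) stop("wide format needs a species column and >= 2 years")
    species <- as.character(df[[1L]])
    if (anyDuplicated(species))
      stop("duplicate species identifier: ",
           species[duplicated(species)][1L])
    yearNames <- names(df)[-1L]
    years <- suppressWarnings(as.integer(sub("^X", "", yearNames)))
    if (anyNA(years)) stop("wide-format year columns must be named by year")
    if (any(diff(years) != 1L)) stop("year columns must be consecutive")
    v <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(v)) stop("abundance values must be numeric")
    speciesDataset(v, years, species = species,
                   provenance = list(path = path, format = "wide"))
  }
}

#' Write a SpeciesDataset to CSV
#'
#' Values are written with 15 significant digits so that a read/write round
#' trip is lossless at that precision.
#'
#' @param dataset a [SpeciesDataset-class].
#' @param path output CSV path.
#' @param format "long" or "wide".
#' @return Invisibly, the path.
#' @export
writeSpeciesDataset <- function(dataset, path, format = c("long", "wide")) {
  format <- match.arg(format)
  v <- abundanceValues(dataset)
  yrs <- datasetYears(dataset)
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (format == "long") {
    df <- data.frame(species = rep(rownames(v), times = ncol(v)),
                     year = rep(yrs, each = nrow(v)),
                     value = fmt(as.vector(v)))
    se <- seValues(dataset)
    if (!is.null(se)) df$se <- fmt(as.vector(se))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(species = rownames(v),
                     apply(v, 2L, fmt), check.names = FALSE)
    names(df) <- c("species", yrs)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a scenario configuration from YAML or JSON
#'
#' The configuration mirrors [scenario()]: a \code{history} block (either a
#' \code{profile} with the [historyProfile()] fields, a preset name in
#' \code{preset}, or a \code{path}/\code{format} pair pointing at a CSV), a
#' \code{sim} block with the [simParams()] fields, and top-level
#' \code{knots}, \code{nRuns}, \code{masterSeed}, \code{presmoothFactor} and
#' optional \code{mcmc} settings. Growth rates are given as multipliers
#' (e.g. 1.01 for +1\% per annum).
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return A list with elements \code{scenario} ([Scenario-class]) and
#'   \code{mcmc} ([McmcConfig-class]).
#' @export
readScenarioConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$history) || is.null(cfg$sim))
    stop("config must contain 'history' and 'sim' blocks")
  history <- if (!is.null(cfg$history$preset)) {
    preset <- match.arg(cfg$history$preset,
                        c("birdLike", "lepidopteraLike", "multiTaxaLike"))
    fn <- switch(preset, birdLike = birdLikeProfile,
                 lepidopteraLike = lepidopteraLikeProfile,
                 multiTaxaLike = multiTaxaLikeProfile)
    if (!is.null(cfg$history$nYears)) fn(nYears = cfg$history$nYears) else fn()
  } else if (!is.null(cfg$history$path)) {
    readSpeciesDataset(cfg$history$path, cfg$history$format %||% "long")
  } else if (!is.null(cfg$history$profile)) {
    do.call(historyProfile, cfg$history$profile)
  } else stop("history block needs 'preset', 'path' or 'profile'")
  sim <- do.call(simParams, cfg$sim)
  scn <- scenario(history, sim,
                  knotsList = as.integer(cfg$knots %||% c(8L, 14L, 20L)),
                  nRuns = as.integer(cfg$nRuns %||% 50L),
                  masterSeed = as.integer(cfg$masterSeed %||% 1L),
                  presmoothFactor = as.numeric(cfg$presmoothFactor %||% 0.3))
  mcmc <- if (is.null(cfg$mcmc)) shortMcmc() else do.call(mcmcConfig, cfg$mcmc)
  list(scenario = scn, mcmc = mcmc)
}

#' Serialize and restore test results and fits
#'
#' \code{writeTestResult} writes a per-year CSV plus decision metadata;
#' \code{writeIndicatorFit}/\code{readIndicatorFit} store a fit as a long
#' draws CSV plus a JSON metadata sidecar, sufficient for exact
#' re-summarisation.
#'
#' @param result a [TestResult-class].
#' @param path output CSV path.
#' @return Invisibly, the path (writers) or the restored object (reader).
#' @export
writeTestResult <- function(result, path) {
  stopifnot(is(result, "TestResult"))
  df <- data.frame(year = result@years, pGeq0 = result@pGeq0)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(result@fitMeta, list(nDraws = result@nDraws))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTestResult
#' @param fit an [IndicatorFit-class].
#' @param dir output directory (created if needed).
#' @export
writeIndicatorFit <- function(fit, dir) {
  stopifnot(is(fit, "IndicatorFit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  eta <- fit@etaDraws
  df <- data.frame(draw = rep(seq_len(nrow(eta)), times = ncol(eta)),
                   year = rep(fit@years[-1L], each = nrow(eta)),
                   eta = formatC(as.vector(eta), digits = 15, format = "g"))
  write.csv(df, file.path(dir, "eta_draws.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(draw = seq_along(fit@sigmaGDraws),
                       sigma_g = formatC(fit@sigmaGDraws, digits = 15,
                                         format = "g")),
            file.path(dir, "sigma_g_draws.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(fit@diagnostics, file.path(dir, "diagnostics.csv"),
            row.names = FALSE, quote = FALSE)
  meta <- list(years = fit@years, nKnots = fit@nKnots,
               converged = fit@converged, meta = fit@meta,
               mcmc = list(nChains = fit@mcmc@nChains, nDraws = fit@mcmc@nDraws,
                           nWarmup = fit@mcmc@nWarmup, nAdapt = fit@mcmc@nAdapt,
                           seed = fit@mcmc@seed,
                           rhatThreshold = fit@mcmc@rhatThreshold))
  meta$meta$params <- NULL
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeTestResult
#' @export
readIndicatorFit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  df <- read.csv(file.path(dir, "eta_draws.csv"))
  years <- as.integer(meta$years)
  nd <- max(df$draw)
  eta <- matrix(df$eta[order(match(df$year, years), df$draw)], nrow = nd,
                dimnames = list(NULL, as.character(years[-1L])))
  sg <- read.csv(file.path(dir, "sigma_g_draws.csv"))$sigma_g
  diag <- read.csv(file.path(dir, "diagnostics.csv"))
  lnI <- cbind(0, rowCumsum(eta))
  ind <- 100 * exp(lnI)
  ind[, 1L] <- 100
  colnames(ind) <- as.character(years)
  mc <- meta$mcmc
  methods::new("IndicatorFit",
    years = years, etaDraws = eta, sigmaGDraws = sg, indicatorDraws = ind,
    nKnots = as.integer(meta$nKnots), diagnostics = diag,
    converged = as.logical(meta$converged),
    mcmc = mcmcConfig(mc$nChains, mc$nDraws, mc$nWarmup, mc$nAdapt, mc$seed,
                      mc$rhatThreshold),
    meta = as.list(meta$meta))
}

#' Write an experiment summary to a directory of CSV files
#'
#' Writes \code{per_run.csv} (run, knots, year, p), \code{mean_p.csv},
#' \code{final_year.csv}, \code{histogram.csv} and \code{failures.csv}. The
#' aggregates are exact functions of the per-run table, so the summary can be
#' recomputed from \code{per_run.csv} alone.
#'
#' @param summary an [ExperimentSummary-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeExperimentSummary <- function(summary, dir) {
  stopifnot(is(summary, "ExperimentSummary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(summary@perRun, file.path(dir, "per_run.csv"), row.names = FALSE)
  write.csv(summary@meanPByYear, file.path(dir, "mean_p.csv"),
            row.names = FALSE)
  write.csv(summary@finalYearP, file.path(dir, "final_year.csv"),
            row.names = FALSE)
  hist <- do.call(rbind, lapply(names(summary@histogram), function(k)
    data.frame(knots = as.integer(k), bin = names(summary@histogram[[k]]),
               count = as.integer(summary@histogram[[k]]))))
  write.csv(hist, file.path(dir, "histogram.csv"), row.names = FALSE)
  write.csv(summary@failures, file.path(dir, "failures.csv"),
            row.names = FALSE)
  invisible(dir)
}
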