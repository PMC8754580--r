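.ALL_METHODS <- c("ivw", "ivw_penalized", "weighted_median", "egger", "mr_lasso")

# Minimum instrument counts per method (soft guards).
.MIN_SNPS <- c(ivw = 1L, ivw_penalized = 2L, weighted_median = 3L,
               egger = 3L, mr_lasso = 3L)

#' Run the full two-sample MR analysis
#'
#' Orchestrates the pipeline: read both summary-statistic files, harmonize to
#' a common effect allele, orient exposure-positive, run the requested
#' estimators, and attach instrument-level heterogeneity diagnostics.
#' Methods whose instrument-count precondition is not met (or that error) are
#' marked failed with the reason; the others proceed.  Deterministic given
#' inputs and seed.
#'
#' @param exposureFile,outcomeFile delimited summary-statistic files
#'   ([readSummaryStats()] layout).
#' @param methods subset of `"ivw"`, `"ivw_penalized"`, `"weighted_median"`,
#'   `"egger"`, `"mr_lasso"`; all five by default.
#' @param config optional list of estimator options: `weights`
#'   (`"first"`/`"second"`), `penaltyScale`, `nBoot`, `lambdaGrid`,
#'   `alphaHet`, `dispersion`, `palindromicWindow`, `exposureName`,
#'   `outcomeName`, `columnMap`.
#' @param seed seed for the weighted-median bootstrap.
#' @return an [MRAnalysisReport-class].
#' @examples
#' dir <- system.file("extdata", package = "frailMR")
#' ## the bundled files carry two traits; in practice each file is one trait
#' exp <- readSummaryStats(file.path(dir, "table1_exposure.tsv"))
#' out <- readSummaryStats(file.path(dir, "table1_outcome.tsv"))
#' @export
runAnalysis <- function(exposureFile, outcomeFile, methods = .ALL_METHODS,
                        config = list(), seed = 1L) {
  methods <- match.arg(methods, .ALL_METHODS, several.ok = TRUE)
  opt <- function(name, default) if (!is.null(config[[name]])) config[[name]] else default

  exposure <- readSummaryStats(exposureFile, columnMap = opt("columnMap", NULL))
  outcome <- readSummaryStats(outcomeFile, columnMap = opt("columnMap", NULL))
  set <- harmonize(exposure, outcome,
                   exposureName = opt("exposureName", "exposure"),
                   outcomeName = opt("outcomeName", "outcome"),
                   palindromicWindow = opt("palindromicWindow", c(0.42, 0.58)))
  set <- orientPositiveExposure(set)
  message(sprintf("harmonized %d instrument(s): %s", length(set),
                  paste(set@snps, collapse = ", ")))

  weights <- opt("weights", "first")
  estimatesList <- list()
  fails <- character(0)
  lasso <- NULL
  for (m in methods) {
    if (length(set) < .MIN_SNPS[[m]]) {
      fails[[m]] <- sprintf("needs >= %d instruments, have %d",
                            .MIN_SNPS[[m]], length(set))
      next
    }
    res <- tryCatch(switch(m,
      ivw = mrIVW(set, weights = weights),
      ivw_penalized = mrPenalizedIVW(set, penaltyScale = opt("penaltyScale", 20),
                                     weights = weights),
      weighted_median = mrWeightedMedian(set, nBoot = opt("nBoot", 1000),
                                         seed = seed),
      egger = mrEgger(set, dispersion = opt("dispersion", "multiplicative")),
      mr_lasso = mrLasso(set, lambdaGrid = opt("lambdaGrid", NULL),
                         alphaHet = opt("alphaHet", 0.01))),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fails[[m]] <- res
    } else if (is(res, "MRLassoFit")) {
      lasso <- res
      estimatesList[[m]] <- res@estimate
      message(sprintf("mr_lasso: lambda %.4g, %d valid / %d invalid",
                      res@lambda, length(res@validSNPs), length(res@invalidSNPs)))
    } else {
      estimatesList[[m]] <- res
    }
  }
  qt <- if (length(set) >= 2L) cochranQ(set) else NULL

  new("MRAnalysisReport", instruments = set, estimates = estimatesList,
      qtest = qt, lasso = lasso, failures = fails,
      provenance = list(exposureFile = exposureFile,
                        outcomeFile = outcomeFile,
                        methods = methods, seed = seed,
                        options = config[setdiff(names(config), "columnMap")],
                        package = as.character(utils::packageVersion("frailMR"))))
}

#' Tabulate the estimates of a report
#'
#' @param report an [MRAnalysisReport-class].
#' @return data.frame with one row per successful method (`method, beta, se,
#'   ci_low, ci_high, pval, n_snps`) plus Egger-intercept columns when
#'   present.
#' @export
estimatesTable <- function(report) {
  rows <- lapply(report@estimates, function(e) {
    ex <- e@extras
    data.frame(method = e@method, beta = e@beta, se = e@se,
               ci_low = e@ciLow, ci_high = e@ciHigh, pval = e@pval,
               n_snps = e@nSNP,
               intercept = if (!is.null(ex$intercept)) ex$intercept else NA_real_,
               intercept_pval = if (!is.null(ex$interceptPval)) ex$interceptPval else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(method = character(0), beta = numeric(0), se = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      pval = numeric(0), n_snps = integer(0),
                      intercept = numeric(0), intercept_pval = numeric(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Serialize a report
#'
#' Writes the estimate table as tab-separated text (re-readable with
#' [readEstimates()]) and, alongside it, a human-readable `.txt` rendering
#' with the provenance block, heterogeneity test, lasso selection and
#' failures.  Output depends only on inputs and seed, so repeated runs are
#' byte-identical.
#'
#' @param report an [MRAnalysisReport-class].
#' @param path output path for the TSV; the text rendering goes to
#'   `sub("tsv$", "txt", path)` when `text = TRUE`.
#' @param text also write the human-readable rendering.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, text = TRUE) {
  tab <- estimatesTable(report)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (text) {
    txt <- c(
      sprintf("MR analysis: %s -> %s", report@instruments@exposureName,
              report@instruments@outcomeName),
      sprintf("instruments (%d): %s", length(report@instruments),
              paste(report@instruments@snps, collapse = ", ")),
      sprintf("seed: %s | package: %s", report@provenance$seed,
              report@provenance$package),
      "",
      utils::capture.output(print(tab, row.names = FALSE, digits = 4)),
      if (!is.null(report@qtest))
        sprintf("heterogeneity: Q = %.4f, df = %d, P = %.4g",
                report@qtest@q, report@qtest@df, report@qtest@pval),
      if (!is.null(report@lasso))
        sprintf("mr_lasso: lambda = %.4g, valid = {%s}, invalid = {%s}",
                report@lasso@lambda,
                paste(report@lasso@validSNPs, collapse = ", "),
                paste(report@lasso@invalidSNPs, collapse = ", ")),
      if (length(report@failures))
        paste("failed:", paste(names(report@failures), report@failures,
                               sep = ": ", collapse = "; ")))
    writeLines(txt, sub("\\.tsv$", ".txt", path))
  }
  invisible(path)
}

#' Re-read a serialized estimate table
#'
#' @param path TSV written by [writeReport()].
#' @return data.frame in the [estimatesTable()] layout.
#' @export
readEstimates <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Published full-sample results the bundled fixture reproduces, with the
# rounded-input tolerances of the reproduction contract.
.REFERENCE <- data.frame(
  quantity = c("albumin_ivw", "albumin_ivw_penalized", "albumin_weighted_median",
               "albumin_egger_slope", "albumin_egger_intercept",
               "albumin_lasso_n_valid", "total_protein_ivw",
               "sex_heterogeneity_p_albumin", "sex_heterogeneity_p_total_protein"),
  published = c(-0.023, -0.120, -0.030, -0.015, -0.001, 6, -0.153, 0.013, 0.952),
  tolerance = c(0.005, 0.03, 0.005, 0.005, 0.002, 0, 0.005, 0.005, 0.005),
  stringsAsFactors = FALSE)

#' Recompute the study's full-sample results from the bundled fixture
#'
#' Runs every estimator on the bundled albumin and total-protein instrument
#' sets and the sex-heterogeneity tests on the published stratum estimates,
#' and compares each computed value side by side with the published one at
#' the documented rounded-input tolerance.
#'
#' @param out optional path; when given, the comparison table is written
#'   there as TSV.
#' @param seed seed for the weighted-median bootstrap (the point estimates
#'   compared here are deterministic).
#' @return data.frame with columns `quantity, computed, published, tolerance,
#'   pass`.
#' @examples
#' reproduceStudy()
#' @export
reproduceStudy <- function(out = NULL, seed = 1L) {
  alb <- table1Fixture("albumin")
  tp <- table1Fixture("total_protein")
  egger <- mrEgger(alb)
  lasso <- mrLasso(alb)
  computed <- c(
    albumin_ivw = mrIVW(alb)@beta,
    albumin_ivw_penalized = mrPenalizedIVW(alb)@beta,
    albumin_weighted_median = mrWeightedMedian(alb, seed = seed)@beta,
    albumin_egger_slope = egger@beta,
    albumin_egger_intercept = egger@extras$intercept,
    albumin_lasso_n_valid = length(lasso@validSNPs),
    total_protein_ivw = mrIVW(tp)@beta,
    # sex-stratified IVW estimates with SEs recovered from the published CIs
    sex_heterogeneity_p_albumin = strataHeterogeneity(
      beta = c(-0.172, 0.123), ciLow = c(-0.336, -0.041),
      ciHigh = c(-0.007, 0.287), labels = c("women", "men"))@pval,
    sex_heterogeneity_p_total_protein = strataHeterogeneity(
      beta = c(-0.148, -0.154), ciLow = c(-0.287, -0.290),
      ciHigh = c(-0.009, -0.018), labels = c("women", "men"))@pval)
  tab <- .REFERENCE
  tab$computed <- unname(computed[tab$quantity])
  tab$pass <- abs(tab$computed - tab$published) <= tab$tolerance
  tab <- tab[c("quantity", "computed", "published", "tolerance", "pass")]
  if (!is.null(out))
    utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = NA),
                       out, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

#' Scatter of outcome vs exposure effects with fitted estimator lines
#'
#' Per-SNP effect plot (the standard MR diagnostic figure): outcome betas
#' against exposure betas with 1-SE error bars, the IVW line through the
#' origin, and the Egger line with its intercept when at least three
#' instruments are available.
#'
#' @param set an [MRInstrumentSet-class].
#' @return a `ggplot` object.
#' @export
plotInstruments <- function(set) {
  df <- as.data.frame(set)
  ivw <- mrIVW(set)
  lines <- data.frame(method = "IVW", intercept = 0, slope = ivw@beta)
  if (length(set) >= 3L && all(set@bx >= 0)) {
    eg <- mrEgger(set)
    lines <- rbind(lines, data.frame(method = "MR-Egger",
                                     intercept = eg@extras$intercept,
                                     slope = eg@beta))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = bx, y = by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = by - sy, ymax = by + sy),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = bx - sx, xmax = bx + sx),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = intercept, slope = slope,
                                      linetype = method)) +
    ggplot2::labs(x = sprintf("SNP effect on %s", set@exposureName),
                  y = sprintf("SNP effect on %s", set@outcomeName),
                  linetype = NULL) +
    ggplot2::theme_minimal()
}
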