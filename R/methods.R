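# Accessors, show and subsetting methods for the S4 containers.

#' @rdname MRInstrumentSet-class
#' @export
setMethod("snps", "MRInstrumentSet", function(x) x@snps)
#' @rdname MRInstrumentSet-class
#' @export
setMethod("exposureName", "MRInstrumentSet", function(x) x@exposureName)
#' @rdname MRInstrumentSet-class
#' @export
setMethod("outcomeName", "MRInstrumentSet", function(x) x@outcomeName)
#' @rdname MRInstrumentSet-class
#' @export
setMethod("exposureBeta", "MRInstrumentSet", function(x) setNames(x@bx, x@snps))
#' @rdname MRInstrumentSet-class
#' @export
setMethod("exposureSE", "MRInstrumentSet", function(x) setNames(x@sx, x@snps))
#' @rdname MRInstrumentSet-class
#' @export
setMethod("outcomeBeta", "MRInstrumentSet", function(x) setNames(x@by, x@snps))
#' @rdname MRInstrumentSet-class
#' @export
setMethod("outcomeSE", "MRInstrumentSet", function(x) setNames(x@sy, x@snps))

#' @rdname MRInstrumentSet-class
#' @export
setMethod("length", "MRInstrumentSet", function(x) length(x@snps))

#' @rdname MRInstrumentSet-class
#' @param i index (numeric, logical, or SNP identifiers).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MRInstrumentSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@snps)
  initialize(x, snps = x@snps[i], bx = x@bx[i], sx = x@sx[i],
             by = x@by[i], sy = x@sy[i], eafX = x@eafX[i])
})

#' @rdname MRInstrumentSet-class
#' @export
setMethod("as.data.frame", "MRInstrumentSet", function(x, ...) {
  data.frame(snp = x@snps, bx = x@bx, sx = x@sx, by = x@by, sy = x@sy,
             eaf_exposure = x@eafX, stringsAsFactors = FALSE)
})

setMethod("show", "MRInstrumentSet", function(object) {
  cat(sprintf("MRInstrumentSet: %s -> %s, %d instrument(s)\n",
              object@exposureName, object@outcomeName, length(object@snps)))
  print(as.data.frame(object), row.names = FALSE, digits = 4)
})

#' @rdname MREstimate-class
#' @export
setMethod("estimate", "MREstimate", function(x) x@beta)
#' @rdname MREstimate-class
#' @export
setMethod("stdError", "MREstimate", function(x) x@se)
#' @rdname MREstimate-class
#' @export
setMethod("pvalue", "MREstimate", function(x) x@pval)
#' @rdname MREstimate-class
#' @export
setMethod("ciLower", "MREstimate", function(x) x@ciLow)
#' @rdname MREstimate-class
#' @export
setMethod("ciUpper", "MREstimate", function(x) x@ciHigh)
#' @rdname MREstimate-class
#' @export
setMethod("mrMethod", "MREstimate", function(x) x@method)
#' @rdname MREstimate-class
#' @export
setMethod("nSNP", "MREstimate", function(x) x@nSNP)
#' @rdname MREstimate-class
#' @export
setMethod("extras", "MREstimate", function(x) x@extras)

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%-16s beta %8.4f  95%% CI (%.4f, %.4f)  P %.4g  [%d SNPs]\n",
              object@method, object@beta, object@ciLow, object@ciHigh,
              object@pval, object@nSNP))
  ex <- object@extras
  if (!is.null(ex$intercept))
    cat(sprintf("  intercept %.4f (SE %.4f, P %.4g)\n",
                ex$intercept, ex$interceptSE, ex$interceptPval))
  if (!is.null(ex$lambda))
    cat(sprintf("  lasso lambda %.4g\n", ex$lambda))
  invisible(NULL)
})

#' @rdname MRLassoFit-class
#' @export
setMethod("validSNPs", "MRLassoFit", function(x) x@validSNPs)
#' @rdname MRLassoFit-class
#' @export
setMethod("invalidSNPs", "MRLassoFit", function(x) x@invalidSNPs)
#' @rdname MRLassoFit-class
#' @export
setMethod("alphas", "MRLassoFit", function(x) x@alphas)
#' @rdname MRLassoFit-class
#' @export
setMethod("lassoLambda", "MRLassoFit", function(x) x@lambda)
#' @rdname MRLassoFit-class
#' @export
setMethod("selectionPath", "MRLassoFit", function(x) x@path)
#' @rdname MRLassoFit-class
#' @export
setMethod("estimate", "MRLassoFit", function(x) x@estimate)

setMethod("show", "MRLassoFit", function(object) {
  cat(sprintf("MRLassoFit: lambda %.4g, %d valid / %d invalid instrument(s)\n",
              object@lambda, length(object@validSNPs), length(object@invalidSNPs)))
  if (length(object@invalidSNPs))
    cat("  invalid:", paste(object@invalidSNPs, collapse = ", "), "\n")
  show(object@estimate)
})

#' @rdname MRQTest-class
#' @export
setMethod("qStatistic", "MRQTest", function(x) x@q)
#' @rdname MRQTest-class
#' @export
setMethod("degreesFreedom", "MRQTest", function(x) x@df)
#' @rdname MRQTest-class
#' @export
setMethod("pvalue", "MRQTest", function(x) x@pval)

setMethod("show", "MRQTest", function(object) {
  cat(sprintf("Cochran's Q = %.4f, df = %d, P = %.4g\n",
              object@q, object@df, object@pval))
})

#' @rdname FrailtyCohort-class
#' @export
setMethod("genotypes", "FrailtyCohort", function(x) x@genotypes)
#' @rdname FrailtyCohort-class
#' @export
setMethod("exposureValues", "FrailtyCohort", function(x) x@exposure)
#' @rdname FrailtyCohort-class
#' @export
setMethod("frailtyIndex", "FrailtyCohort", function(x) x@fi)
#' @rdname FrailtyCohort-class
#' @export
setMethod("covariates", "FrailtyCohort", function(x)
  data.frame(age = x@age, sex = x@sex))
#' @rdname FrailtyCohort-class
#' @export
setMethod("length", "FrailtyCohort", function(x) nrow(x@genotypes))

setMethod("show", "FrailtyCohort", function(object) {
  cat(sprintf(paste0(
    "FrailtyCohort: %d individuals, %d SNPs\n",
    "  exposure mean %.2f (SD %.2f) | FI mean %.2f%% (SD %.2f%%) | %.1f%% female\n"),
    nrow(object@genotypes), ncol(object@genotypes),
    mean(object@exposure), sd(object@exposure),
    mean(object@fi), sd(object@fi), 100 * mean(object@sex)))
})

#' @rdname MRAnalysisReport-class
#' @export
setMethod("estimates", "MRAnalysisReport", function(x) x@estimates)
#' @rdname MRAnalysisReport-class
#' @export
setMethod("failures", "MRAnalysisReport", function(x) x@failures)
#' @rdname MRAnalysisReport-class
#' @export
setMethod("provenance", "MRAnalysisReport", function(x) x@provenance)
#' @rdname MRAnalysisReport-class
#' @export
setMethod("instruments", "MRAnalysisReport", function(x) x@instruments)
#' @rdname MRAnalysisReport-class
#' @export
setMethod("lassoFit", "MRAnalysisReport", function(x) x@lasso)
#' @rdname MRAnalysisReport-class
#' @export
setMethod("qTest", "MRAnalysisReport", function(x) x@qtest)

setMethod("show", "MRAnalysisReport", function(object) {
  cat(sprintf("MR analysis: %s -> %s (%d instruments)\n",
              object@instruments@exposureName, object@instruments@outcomeName,
              length(object@instruments)))
  tab <- estimatesTable(object)
  if (nrow(tab)) print(tab, row.names = FALSE, digits = 4)
  if (!is.null(object@qtest)) show(object@qtest)
  if (length(object@failures))
    cat("failed:", paste(names(object@failures), object@failures,
                         sep = ": ", collapse = "; "), "\n")
})
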