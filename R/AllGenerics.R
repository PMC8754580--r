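#' @rdname MRInstrumentSet-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("snps", function(x) standardGeneric("snps"))
#' @rdname MRInstrumentSet-class
#' @export
setGeneric("exposureName", function(x) standardGeneric("exposureName"))
#' @rdname MRInstrumentSet-class
#' @export
setGeneric("outcomeName", function(x) standardGeneric("outcomeName"))
#' @rdname MRInstrumentSet-class
#' @export
setGeneric("exposureBeta", function(x) standardGeneric("exposureBeta"))
#' @rdname MRInstrumentSet-class
#' @export
setGeneric("exposureSE", function(x) standardGeneric("exposureSE"))
#' @rdname MRInstrumentSet-class
#' @export
setGeneric("outcomeBeta", function(x) standardGeneric("outcomeBeta"))
#' @rdname MRInstrumentSet-class
#' @export
setGeneric("outcomeSE", function(x) standardGeneric("outcomeSE"))

#' @rdname MREstimate-class
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))
#' @rdname MREstimate-class
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))
#' @rdname MREstimate-class
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))
#' @rdname MREstimate-class
#' @export
setGeneric("ciLower", function(x) standardGeneric("ciLower"))
#' @rdname MREstimate-class
#' @export
setGeneric("ciUpper", function(x) standardGeneric("ciUpper"))
#' @rdname MREstimate-class
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))
#' @rdname MREstimate-class
#' @export
setGeneric("nSNP", function(x) standardGeneric("nSNP"))
#' @rdname MREstimate-class
#' @export
setGeneric("extras", function(x) standardGeneric("extras"))

#' @rdname MRLassoFit-class
#' @export
setGeneric("validSNPs", function(x) standardGeneric("validSNPs"))
#' @rdname MRLassoFit-class
#' @export
setGeneric("invalidSNPs", function(x) standardGeneric("invalidSNPs"))
#' @rdname MRLassoFit-class
#' @export
setGeneric("alphas", function(x) standardGeneric("alphas"))
#' @rdname MRLassoFit-class
#' @export
setGeneric("lassoLambda", function(x) standardGeneric("lassoLambda"))
#' @rdname MRLassoFit-class
#' @export
setGeneric("selectionPath", function(x) standardGeneric("selectionPath"))

#' @rdname MRQTest-class
#' @export
setGeneric("qStatistic", function(x) standardGeneric("qStatistic"))
#' @rdname MRQTest-class
#' @export
setGeneric("degreesFreedom", function(x) standardGeneric("degreesFreedom"))

#' @rdname FrailtyCohort-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname FrailtyCohort-class
#' @export
setGeneric("exposureValues", function(x) standardGeneric("exposureValues"))
#' @rdname FrailtyCohort-class
#' @export
setGeneric("frailtyIndex", function(x) standardGeneric("frailtyIndex"))
#' @rdname FrailtyCohort-class
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname MRAnalysisReport-class
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))
#' @rdname MRAnalysisReport-class
#' @export
setGeneric("failures", function(x) standardGeneric("failures"))
#' @rdname MRAnalysisReport-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname MRAnalysisReport-class
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))
#' @rdname MRAnalysisReport-class
#' @export
setGeneric("lassoFit", function(x) standardGeneric("lassoFit"))
#' @rdname MRAnalysisReport-class
#' @export
setGeneric("qTest", function(x) standardGeneric("qTest"))
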