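#' Instrument-level Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (theta_j - theta_IVW)^2` over the per-SNP ratio estimates
#' with first-order inverse-variance weights, referred to the chi-squared
#' distribution with `J - 1` degrees of freedom.  Identically the weighted
#' residual sum of squares of the origin-constrained WLS fit underlying
#' [mrIVW()].
#'
#' @param set an [MRInstrumentSet-class] with at least two instruments.
#' @return an [MRQTest-class].
#' @examples
#' cochranQ(table1Fixture("albumin"))
#' @export
cochranQ <- function(set) {
  if (length(set) < 2L)
    stop("Cochran's Q needs at least 2 instruments", call. = FALSE)
  r <- ratioEstimates(set)
  theta <- sum(r$w * r$theta) / sum(r$w)
  q <- sum(r$w * (r$theta - theta)^2)
  df <- length(set) - 1L
  new("MRQTest", q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
}

#' Recover a standard error from a printed 95% confidence interval
#'
#' `se = (high - low) / (2 * 1.959964)`, the inverse of the normal-quantile
#' interval construction.  Used to feed published stratum estimates into
#' [strataHeterogeneity()].
#'
#' @param low,high interval bounds (vectorized); must be finite with
#'   `high > low`.
#' @return standard error(s).
#' @examples
#' seFromCI(-0.336, -0.007)
#' @export
seFromCI <- function(low, high) {
  if (any(!is.finite(low)) || any(!is.finite(high)))
    stop("CI bounds must be finite", call. = FALSE)
  if (any(high <= low)) stop("high must exceed low", call. = FALSE)
  (high - low) / (2 * Z95)
}

#' Between-stratum heterogeneity (Cochran's Q)
#'
#' Tests whether stratum-specific causal estimates (e.g. women vs men) share
#' a common value: the strata are pooled by fixed-effect inverse-variance
#' weighting, and `Q = sum (theta_k - pooled)^2 / se_k^2` is referred to
#' chi-squared with `K - 1` degrees of freedom.
#'
#' @param beta numeric vector of stratum estimates (length >= 2).
#' @param se their standard errors, or `NULL` if `ciLow`/`ciHigh` are given.
#' @param ciLow,ciHigh optional 95% CI bounds from which SEs are recovered
#'   via [seFromCI()].
#' @param labels optional stratum labels (for error messages/reports only).
#' @return an [MRQTest-class].
#' @examples
#' # sex-stratified albumin estimates, SEs recovered from printed CIs
#' strataHeterogeneity(beta = c(-0.172, 0.123),
#'                     ciLow = c(-0.336, -0.041), ciHigh = c(-0.007, 0.287))
#' @export
strataHeterogeneity <- function(beta, se = NULL, ciLow = NULL, ciHigh = NULL,
                                labels = NULL) {
  if (is.null(se)) {
    if (is.null(ciLow) || is.null(ciHigh))
      stop("provide either se or both ciLow and ciHigh", call. = FALSE)
    se <- seFromCI(ciLow, ciHigh)
  }
  K <- length(beta)
  if (K < 2L) stop("need at least 2 strata", call. = FALSE)
  if (length(se) != K) stop("beta and se lengths differ", call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("stratum SEs must be finite and > 0", call. = FALSE)
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - pooled)^2)
  df <- K - 1L
  new("MRQTest", q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
}

#' Read a stratum-estimate table
#'
#' Small delimited table with header and columns `label`, `beta`, and either
#' `se` or `ci_low`/`ci_high`, as consumed by [strataHeterogeneity()].
#'
#' @param path path to a tab- or comma-delimited file.
#' @return data.frame with columns `label`, `beta`, `se`.
#' @export
readStrataTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("label", "beta") %in% names(tab)))
    stop("strata table needs 'label' and 'beta' columns", call. = FALSE)
  if (!"se" %in% names(tab)) {
    if (!all(c("ci_low", "ci_high") %in% names(tab)))
      stop("strata table needs 'se' or 'ci_low'/'ci_high' columns",
           call. = FALSE)
    tab$se <- seFromCI(tab$ci_low, tab$ci_high)
  }
  tab[c("label", "beta", "se")]
}

#' Leave-one-out IVW table
#'
#' Recomputes the fixed-effect IVW estimate excluding each instrument in
#' turn; a quick per-SNP influence diagnostic.
#'
#' @param set an [MRInstrumentSet-class] with at least three instruments.
#' @return data.frame with columns `excluded`, `beta`, `se`, `pval`.
#' @export
leaveOneOut <- function(set) {
  if (length(set) < 3L)
    stop("leave-one-out needs at least 3 instruments", call. = FALSE)
  rows <- lapply(seq_along(set@snps), function(i) {
    fit <- mrIVW(set[-i])
    data.frame(excluded = set@snps[i], beta = fit@beta, se = fit@se,
               pval = fit@pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
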