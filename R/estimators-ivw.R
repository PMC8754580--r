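Z95 <- 1.959964  # normal 97.5% quantile, fixed by convention

.mrEstimate <- function(method, beta, se, pval, nSNP, extras = list()) {
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - Z95 * se, ciHigh = beta + Z95 * se,
      pval = pval, nSNP = as.integer(nSNP), extras = extras)
}

# First- or second-order inverse-variance weights of the ratio estimates.
.ivwWeights <- function(set, weights = c("first", "second")) {
  weights <- match.arg(weights)
  if (weights == "first") set@bx^2 / set@sy^2
  else 1 / (set@sy^2 / set@bx^2 + set@by^2 * set@sx^2 / set@bx^4)
}

#' Per-SNP ratio (Wald) estimates
#'
#' For each instrument, the causal-effect ratio `theta_j = by_j / bx_j`, its
#' first-order delta-method standard error `se_j = sy_j / |bx_j|`, and the
#' inverse-variance weight `w_j = 1 / se_j^2 = bx_j^2 / sy_j^2`.
#'
#' @param set an [MRInstrumentSet-class]; all `bx` must be non-zero.
#' @return data.frame with columns `snp, theta, se, w`.
#' @examples
#' ratioEstimates(table1Fixture("total_protein"))
#' @export
ratioEstimates <- function(set) {
  zero <- set@bx == 0
  if (any(zero))
    stop("degenerate instrument(s) with zero exposure effect: ",
         paste(set@snps[zero], collapse = ", "), call. = FALSE)
  data.frame(snp = set@snps,
             theta = set@by / set@bx,
             se = set@sy / abs(set@bx),
             w = set@bx^2 / set@sy^2,
             stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance-weighted (IVW) estimator
#'
#' The weighted average of the per-SNP ratio estimates with first-order
#' inverse-variance weights,
#' `theta = sum(bx*by/sy^2) / sum(bx^2/sy^2)`, and the fixed-effect standard
#' error `(sum w)^(-1/2)` with no residual-scale inflation.  Equivalent to
#' weighted least squares of `by` on `bx` through the origin with weights
#' `1/sy^2`.  Two-sided normal p-value.
#'
#' @param set an [MRInstrumentSet-class] with at least one instrument.
#' @param weights `"first"` (default) for first-order weights `bx^2/sy^2`,
#'   `"second"` to add the exposure-side variance term.
#' @return an [MREstimate-class] with method `"ivw"`.
#' @examples
#' mrIVW(table1Fixture("total_protein"))
#' @export
mrIVW <- function(set, weights = c("first", "second")) {
  r <- ratioEstimates(set)
  w <- .ivwWeights(set, weights)
  beta <- sum(w * r$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  .mrEstimate("ivw", beta, se, 2 * pnorm(-abs(beta / se)), length(set),
              extras = list(weights = match.arg(weights)))
}

#' IVW with penalized weights
#'
#' Downweights instruments with outlying ratio estimates in a single pass:
#' from the fixed-effect IVW fit, each instrument's heterogeneity
#' contribution `q_j = w_j (theta_j - theta_IVW)^2` is referred to the
#' chi-squared(1) upper tail, and the weight is multiplied by
#' `min(1, penaltyScale * p_j)`.  Instruments consistent with the pooled
#' estimate (tail probability at least `1/penaltyScale`) keep their full
#' weight, so in the absence of outliers the estimate equals [mrIVW()].
#'
#' @param set an [MRInstrumentSet-class] with at least two instruments.
#' @param penaltyScale multiplier of the chi-squared tail probability;
#'   default 20 (weights are only penalized when `p_j < 0.05`).
#' @param weights weight order, as in [mrIVW()].
#' @return an [MREstimate-class] with method `"ivw_penalized"`; `extras`
#'   carries the per-SNP penalty factors.
#' @examples
#' mrPenalizedIVW(table1Fixture("albumin"))
#' @export
mrPenalizedIVW <- function(set, penaltyScale = 20, weights = c("first", "second")) {
  if (length(set) < 2L)
    stop("penalized IVW needs at least 2 instruments", call. = FALSE)
  r <- ratioEstimates(set)
  w <- .ivwWeights(set, weights)
  theta0 <- sum(w * r$theta) / sum(w)
  q <- w * (r$theta - theta0)^2
  penalty <- pmin(1, penaltyScale * pchisq(q, df = 1, lower.tail = FALSE))
  ws <- w * penalty
  beta <- sum(ws * r$theta) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  .mrEstimate("ivw_penalized", beta, se, 2 * pnorm(-abs(beta / se)),
              length(set),
              extras = list(penaltyScale = penaltyScale,
                            penaltyFactor = setNames(penalty, set@snps)))
}
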