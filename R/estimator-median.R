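# Weighted median of values `theta` with weights `w`: order the values,
# form normalized midpoint cumulative ranks s_j = (cum_j - w_j/2)/sum(w),
# and linearly interpolate theta over s at 0.5.  Ties in theta are broken
# by `ids` for determinism.
.weightedMedian <- function(theta, w, ids = seq_along(theta)) {
  o <- order(theta, ids)
  theta <- theta[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(s)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Consistent estimate of the causal effect when instruments carrying at
#' least half of the total weight are valid.  The point estimate is the
#' inverse-variance-weighted median of the per-SNP ratio estimates
#' (midpoint-rank interpolation at 0.5); its standard error is obtained by
#' parametric bootstrap, resampling `bx_j ~ N(bx_j, sx_j)` and
#' `by_j ~ N(by_j, sy_j)` and recomputing the weighted median each time.
#' The point estimate is deterministic; only the SE depends on the RNG.
#'
#' @param set an [MRInstrumentSet-class] with at least three instruments.
#' @param nBoot bootstrap iterations for the SE (default 1000).
#' @param seed optional integer seed for the bootstrap, applied locally
#'   without disturbing the caller's RNG state.
#' @return an [MREstimate-class] with method `"weighted_median"`; `extras`
#'   records `nBoot` and the seed.
#' @examples
#' mrWeightedMedian(table1Fixture("albumin"), seed = 1)
#' @export
mrWeightedMedian <- function(set, nBoot = 1000, seed = NULL) {
  if (length(set) < 3L)
    stop("weighted median needs at least 3 instruments", call. = FALSE)
  r <- ratioEstimates(set)
  beta <- .weightedMedian(r$theta, r$w, set@snps)

  J <- length(set)
  boot <- local({
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    bxs <- matrix(rnorm(J * nBoot, set@bx, set@sx), nrow = J)
    bys <- matrix(rnorm(J * nBoot, set@by, set@sy), nrow = J)
    vapply(seq_len(nBoot), function(b) {
      .weightedMedian(bys[, b] / bxs[, b], bxs[, b]^2 / set@sy^2, set@snps)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  .mrEstimate("weighted_median", beta, se, 2 * pnorm(-abs(beta / se)), J,
              extras = list(nBoot = nBoot, seed = seed))
}
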