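#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects with
#' a free intercept and weights `1/sy^2`.  The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional pleiotropic effect per instrument, and its test (zero under
#' the InSIDE assumption with balanced pleiotropy) is reported in `extras`.
#' Requires the exposure-positive orientation of
#' [orientPositiveExposure()] — the fit is not invariant to per-SNP sign
#' flips, so the convention must be fixed beforehand; an error is raised if
#' any `bx < 0`.
#'
#' Standard errors come from the WLS normal equations scaled by the
#' multiplicative dispersion `max(1, Q_E/(J-2))` (`dispersion =
#' "multiplicative"`, the default) or left unscaled (`"fixed"`), where `Q_E`
#' is the weighted residual sum of squares.  P-values use the t distribution
#' with `J - 2` degrees of freedom.  The `ciLow/ciHigh` slots keep the
#' package-wide normal-quantile convention; t-quantile bounds are provided in
#' `extras$ciLowT`/`extras$ciHighT`.
#'
#' @param set an [MRInstrumentSet-class] with at least three instruments,
#'   oriented exposure-positive.
#' @param dispersion `"multiplicative"` or `"fixed"`.
#' @return an [MREstimate-class] with method `"egger"`; `extras` carries
#'   `intercept`, `interceptSE`, `interceptPval`, `dispersion`, `df` and the
#'   t-quantile CI of the slope.
#' @examples
#' mrEgger(table1Fixture("albumin"))
#' @export
mrEgger <- function(set, dispersion = c("multiplicative", "fixed")) {
  dispersion <- match.arg(dispersion)
  J <- length(set)
  if (J < 3L) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  if (any(set@bx < 0))
    stop("MR-Egger requires exposure-positive orientation; ",
         "apply orientPositiveExposure() first", call. = FALSE)
  w <- 1 / set@sy^2
  x <- set@bx; y <- set@by
  sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
  det <- sw * swx2 - swx^2
  if (abs(det) < 1e-12 * sw * swx2 || length(unique(x)) == 1L)
    stop("singular design: exposure effects are (nearly) identical",
         call. = FALSE)
  slope <- (sw * sum(w * x * y) - swx * sum(w * y)) / det
  intercept <- (sum(w * y) - slope * swx) / sw
  resid <- y - intercept - slope * x
  qE <- sum(w * resid^2)
  df <- J - 2L
  phi <- if (dispersion == "multiplicative") max(1, qE / df) else 1
  seSlope <- sqrt(phi * sw / det)
  seIntercept <- sqrt(phi * swx2 / det)
  pSlope <- 2 * pt(-abs(slope / seSlope), df)
  pIntercept <- 2 * pt(-abs(intercept / seIntercept), df)
  tq <- qt(0.975, df)
  .mrEstimate("egger", slope, seSlope, pSlope, J,
              extras = list(intercept = intercept, interceptSE = seIntercept,
                            interceptPval = pIntercept,
                            dispersion = phi, df = df, qE = qE,
                            ciLowT = slope - tq * seSlope,
                            ciHighT = slope + tq * seSlope))
}
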