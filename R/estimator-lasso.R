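# Soft-threshold operator.
.soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Coordinate descent for min_theta,alpha sum_j (by_j - a_j - theta bx_j)^2/sy_j^2
# + lambda * sum_j |a_j|.  Alpha update: soft-threshold of the residual at
# lambda*sy_j^2/2; theta update: IVW on the alpha-adjusted outcomes.
.lassoFit <- function(lambda, bx, by, sy, tol = 1e-10, maxit = 10000L) {
  v <- 1 / sy^2
  theta <- sum(v * bx * by) / sum(v * bx^2)
  a <- rep(0, length(bx))
  for (it in seq_len(maxit)) {
    a_new <- .soft(by - theta * bx, lambda / (2 * v))
    theta_new <- sum(v * bx * (by - a_new)) / sum(v * bx^2)
    done <- max(abs(c(a_new - a, theta_new - theta))) < tol * (1 + abs(theta))
    a <- a_new; theta <- theta_new
    if (done) break
  }
  list(alpha = a, theta = theta)
}

#' MR-Lasso: instrument selection via L1-penalized pleiotropy intercepts
#'
#' Fits, for each candidate penalty `lambda`, the model
#' `by_j = alpha_j + theta * bx_j` by coordinate descent with weights
#' `1/sy_j^2` and an L1 penalty on the per-SNP intercepts `alpha_j`.
#' Instruments with `alpha_j = 0` form the valid set.  `lambda` is chosen by
#' the heterogeneity stopping rule: a log-spaced grid is scanned downward
#' from `lambda_max` (the smallest penalty at which every intercept is zero,
#' available in closed form from the soft-threshold conditions), stopping at
#' the first `lambda` whose valid set is internally homogeneous — its
#' fixed-effect IVW Cochran Q not exceeding the upper `alphaHet` chi-squared
#' critical value on `|V| - 1` degrees of freedom.  The causal effect is then
#' re-estimated by fixed-effect IVW on the selected valid set (post-lasso
#' estimator).
#'
#' The default `alphaHet = 0.01` discards instruments only on strong evidence
#' of heterogeneity; borderline heterogeneity (tail probability between 1%
#' and 5%) does not trigger exclusion.  Set `alphaHet = 0.05` for the more
#' aggressive conventional threshold.
#'
#' @param set an [MRInstrumentSet-class] with at least three instruments.
#' @param lambdaGrid optional decreasing vector of penalties; by default 50
#'   log-spaced values from `lambda_max` down to `lambda_max * 1e-4`.
#' @param alphaHet significance level of the heterogeneity stopping rule.
#' @param tol relative convergence tolerance of the coordinate descent.
#' @return an [MRLassoFit-class]; `estimate(fit)` is the post-lasso
#'   [MREstimate-class] (method `"post_lasso_ivw"`), and `selectionPath(fit)`
#'   logs the scan.
#' @examples
#' fit <- mrLasso(table1Fixture("albumin"))
#' validSNPs(fit)
#' @export
mrLasso <- function(set, lambdaGrid = NULL, alphaHet = 0.01, tol = 1e-10) {
  J <- length(set)
  if (J < 3L) stop("MR-Lasso needs at least 3 instruments", call. = FALSE)
  bx <- set@bx; by <- set@by; sy <- set@sy
  v <- 1 / sy^2
  theta0 <- sum(v * bx * by) / sum(v * bx^2)
  if (is.null(lambdaGrid)) {
    lmax <- max(2 * v * abs(by - theta0 * bx))
    if (lmax < 1e-12) {
      # exact fit: every intercept is zero at any penalty
      post <- mrIVW(set)
      post@method <- "post_lasso_ivw"
      post@extras <- list(lambda = 0, alphaHet = alphaHet, nValid = J)
      validObject(post)
      return(new("MRLassoFit", alphas = setNames(rep(0, J), set@snps),
                 lambda = 0, validSNPs = set@snps,
                 invalidSNPs = character(0), estimate = post,
                 path = data.frame(lambda = 0, nValid = J, q = 0,
                                   crit = qchisq(1 - alphaHet, df = J - 1L))))
    }
    lambdaGrid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 50))
  } else {
    lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
  }

  path <- data.frame(lambda = numeric(0), nValid = integer(0),
                     q = numeric(0), crit = numeric(0))
  selected <- NULL
  for (lam in lambdaGrid) {
    fit <- .lassoFit(lam, bx, by, sy, tol = tol)
    valid <- which(fit$alpha == 0)
    if (length(valid) < 2L) {
      path <- rbind(path, data.frame(lambda = lam, nValid = length(valid),
                                     q = NA_real_, crit = NA_real_))
      next
    }
    w <- bx[valid]^2 / sy[valid]^2
    th <- by[valid] / bx[valid]
    thetaV <- sum(w * th) / sum(w)
    q <- sum(w * (th - thetaV)^2)
    crit <- qchisq(1 - alphaHet, df = length(valid) - 1L)
    path <- rbind(path, data.frame(lambda = lam, nValid = length(valid),
                                   q = q, crit = crit))
    if (q <= crit) { selected <- list(lambda = lam, fit = fit, valid = valid); break }
  }
  if (is.null(selected))
    stop("lasso selection failed: no lambda on the grid yields a ",
         "homogeneous valid set of at least 2 instruments", call. = FALSE)

  alpha <- setNames(selected$fit$alpha, set@snps)
  validIds <- set@snps[selected$valid]
  post <- mrIVW(set[selected$valid])
  post@method <- "post_lasso_ivw"
  post@extras <- list(lambda = selected$lambda, alphaHet = alphaHet,
                      nValid = length(validIds))
  validObject(post)
  new("MRLassoFit", alphas = alpha, lambda = selected$lambda,
      validSNPs = validIds,
      invalidSNPs = setdiff(set@snps, validIds),
      estimate = post, path = path)
}
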