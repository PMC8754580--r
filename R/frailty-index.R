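#' Deficit-accumulation frailty index
#'
#' The Rockwood frailty index of each individual: the sum of deficit scores
#' divided by the total number of deficits considered, expressed as a
#' percentage.  Deficits are usually binary (present/absent) but graded
#' values in \[0, 1\] are accepted (Rockwood convention).  The matrix must be
#' complete — individuals with missing deficit information are excluded
#' upstream (complete-case analysis).
#'
#' @param deficits numeric matrix or data.frame, individuals x deficits, all
#'   entries in \[0, 1\], no missing values.
#' @param totalDeficits the deficit count the index is scaled by; defaults to
#'   49 (the catalogue size of the motivating cohort) and to `ncol(deficits)`
#'   when fewer columns are supplied deliberately, pass it explicitly.
#' @return numeric vector of FI values in percent, one per row.
#' @examples
#' m <- matrix(0, 1, 49); m[1, 1:10] <- 1
#' computeFI(m)  # 10 of 49 deficits -> 20.4%
#' @export
computeFI <- function(deficits, totalDeficits = 49) {
  deficits <- as.matrix(deficits)
  if (anyNA(deficits))
    stop("deficit matrix must be complete (complete-case analysis)",
         call. = FALSE)
  if (any(deficits < 0 | deficits > 1))
    stop("deficit scores must lie in [0,1]", call. = FALSE)
  if (totalDeficits < ncol(deficits))
    stop("totalDeficits cannot be smaller than the number of deficit columns",
         call. = FALSE)
  100 * rowSums(deficits) / totalDeficits
}

# Closed-form OLS of y on design X; returns per-coefficient estimate/SE/p.
.ols <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design", call. = FALSE)
  coefs <- qr.coef(qrX, y)
  resid <- y - X %*% coefs
  dfres <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / dfres
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  list(beta = coefs, se = se, pval = 2 * pt(-abs(coefs / se), dfres))
}

#' Per-SNP regression of the frailty index on genotype dosage
#'
#' The outcome-side GWAS stage of the analysis: for each SNP, ordinary least
#' squares of the FI (in percent) on effect-allele dosage under an additive
#' model, adjusted for age (continuous) and sex, returning the per-allele
#' effect, SE, p-value and sample size as outcome summary statistics.
#' Stratified modes fit within stratum: by sex (adjusting for age only) or by
#' age group (<60 / >=60 years, adjusting for sex).
#'
#' @param genotypes n x J dosage matrix (0/1/2, or \[0, 2\] for imputed
#'   dosages), SNP ids as column names.
#' @param fi per-individual frailty index in percent.
#' @param covariates data.frame with columns `age` (years, > 0) and `sex`
#'   (binary, 1 = female).
#' @param stratify `"none"` (default), `"sex"`, or `"age60"`.
#' @return data.frame with columns `snp, beta, se, pval, n`, plus `stratum`
#'   when stratified.
#' @export
snpFIRegression <- function(genotypes, fi, covariates,
                            stratify = c("none", "sex", "age60")) {
  stratify <- match.arg(stratify)
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (length(fi) != n || nrow(covariates) != n)
    stop("genotypes, fi and covariates must agree in length", call. = FALSE)
  if (any(genotypes < 0 | genotypes > 2))
    stop("dosages must lie in [0,2]", call. = FALSE)
  if (!all(c("age", "sex") %in% names(covariates)))
    stop("covariates must have 'age' and 'sex' columns", call. = FALSE)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))

  strata <- switch(stratify,
    none = list(all = rep(TRUE, n)),
    sex = list(women = covariates$sex == 1, men = covariates$sex == 0),
    age60 = list(`age<60` = covariates$age < 60,
                 `age>=60` = covariates$age >= 60))

  rows <- list()
  for (sname in names(strata)) {
    idx <- strata[[sname]]
    if (!any(idx)) next
    covs <- switch(stratify,
      none = cbind(age = covariates$age[idx], sex = covariates$sex[idx]),
      sex = cbind(age = covariates$age[idx]),
      age60 = cbind(sex = covariates$sex[idx]))
    yi <- fi[idx]
    for (j in seq_along(ids)) {
      g <- genotypes[idx, j]
      if (length(unique(g)) == 1L)
        stop("constant dosage for SNP ", ids[j],
             ": per-allele effect undefined", call. = FALSE)
      fit <- .ols(cbind(1, g, covs), yi)
      rows[[length(rows) + 1L]] <- data.frame(
        snp = ids[j], beta = unname(fit$beta[2]), se = unname(fit$se[2]),
        pval = unname(fit$pval[2]), n = sum(idx), stratum = sname,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (stratify == "none") out$stratum <- NULL
  rownames(out) <- NULL
  out
}
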