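#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Harmonized instrument set for two-sample Mendelian randomization
#'
#' Holds, for one exposure/outcome pair, the per-SNP genetic associations
#' after harmonization to a common effect allele: exposure betas (`bx`, in
#' exposure units per effect allele, here g/L), their standard errors (`sx`),
#' and outcome betas (`by`, frailty-index percentage points per allele) with
#' standard errors (`sy`).  All five MR estimators in the package operate on
#' this container.
#'
#' @slot exposureName label of the exposure trait (e.g. "serum albumin").
#' @slot outcomeName label of the outcome trait.
#' @slot snps character vector of unique SNP identifiers (rsIDs).
#' @slot bx,sx numeric vectors: per-allele exposure effect and its SE.
#' @slot by,sy numeric vectors: per-allele outcome effect and its SE.
#' @slot eafX effect-allele frequency on the exposure side (`NA` allowed).
#'
#' @seealso [harmonize()], [table1Fixture()], [mrIVW()]
#' @export
setClass("MRInstrumentSet",
  representation(
    exposureName = "character",
    outcomeName  = "character",
    snps = "character",
    bx = "numeric", sx = "numeric",
    by = "numeric", sy = "numeric",
    eafX = "numeric"
  ),
  prototype(exposureName = "exposure", outcomeName = "outcome")
)

setValidity("MRInstrumentSet", function(object) {
  n <- length(object@snps)
  msg <- character(0)
  if (n < 1L) msg <- c(msg, "an instrument set needs at least 1 SNP")
  if (anyDuplicated(object@snps)) msg <- c(msg, "SNP identifiers must be unique")
  lens <- c(length(object@bx), length(object@sx), length(object@by),
            length(object@sy), length(object@eafX))
  if (any(lens != n)) msg <- c(msg, "slot lengths disagree with number of SNPs")
  if (any(!is.finite(object@sx)) || any(object@sx <= 0))
    msg <- c(msg, "exposure SEs must be finite and > 0")
  if (any(!is.finite(object@sy)) || any(object@sy <= 0))
    msg <- c(msg, "outcome SEs must be finite and > 0")
  if (any(!is.finite(object@bx)) || any(!is.finite(object@by)))
    msg <- c(msg, "betas must be finite")
  if (any(!is.na(object@eafX) & (object@eafX <= 0 | object@eafX >= 1)))
    msg <- c(msg, "effect-allele frequencies must lie in (0,1) when present")
  if (length(msg)) msg else TRUE
})

#' A causal-effect estimate from one MR method
#'
#' @slot method one of `"ivw"`, `"ivw_penalized"`, `"weighted_median"`,
#'   `"egger"`, `"post_lasso_ivw"`.
#' @slot beta causal effect estimate (outcome units per exposure unit; here
#'   FI percentage points per g/L).
#' @slot se standard error of `beta`.
#' @slot ciLow,ciHigh normal-quantile 95% confidence bounds,
#'   `beta ± 1.959964 * se`.
#' @slot pval two-sided p-value.
#' @slot nSNP number of instruments used.
#' @slot extras method-specific values (Egger intercept and its SE/p,
#'   dispersion and degrees of freedom; lasso lambda; bootstrap settings).
#' @export
setClass("MREstimate",
  representation(
    method = "character",
    beta = "numeric", se = "numeric",
    ciLow = "numeric", ciHigh = "numeric",
    pval = "numeric", nSNP = "integer",
    extras = "list"
  )
)

setValidity("MREstimate", function(object) {
  msg <- character(0)
  z <- 1.959964
  if (!is.finite(object@se) || object@se <= 0) msg <- c(msg, "se must be > 0")
  if (is.finite(object@se)) {
    tol <- 1e-6 * max(1, object@se)
    if (abs(object@ciLow  - (object@beta - z * object@se)) > tol ||
        abs(object@ciHigh - (object@beta + z * object@se)) > tol)
      msg <- c(msg, "CI bounds must equal beta -/+ 1.959964*se")
    if (object@ciLow >= object@ciHigh) msg <- c(msg, "ciLow must be < ciHigh")
  }
  if (object@nSNP < 1L) msg <- c(msg, "nSNP must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MR-Lasso fit: per-SNP pleiotropy intercepts and the selected valid set
#'
#' @slot alphas named numeric vector of per-SNP pleiotropy intercepts at the
#'   selected tuning parameter (zero = valid instrument).
#' @slot lambda selected L1 penalty.
#' @slot validSNPs,invalidSNPs partition of the SNP identifiers.
#' @slot estimate the post-lasso [MREstimate-class] (fixed-effect IVW
#'   restricted to the valid set).
#' @slot path data.frame logging the lambda scan (lambda, number valid,
#'   heterogeneity Q of the valid set, critical value).
#' @export
setClass("MRLassoFit",
  representation(
    alphas = "numeric", lambda = "numeric",
    validSNPs = "character", invalidSNPs = "character",
    estimate = "MREstimate", path = "data.frame"
  )
)

setValidity("MRLassoFit", function(object) {
  msg <- character(0)
  all_ids <- sort(names(object@alphas))
  if (!identical(sort(c(object@validSNPs, object@invalidSNPs)), all_ids))
    msg <- c(msg, "validSNPs and invalidSNPs must partition the SNP set")
  if (length(intersect(object@validSNPs, object@invalidSNPs)))
    msg <- c(msg, "validSNPs and invalidSNPs must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Cochran's Q heterogeneity test
#'
#' @slot q Q statistic (weighted sum of squared deviations from the pooled
#'   fixed-effect estimate).
#' @slot df degrees of freedom (number of estimates minus one).
#' @slot pval upper-tail chi-squared probability.
#' @export
setClass("MRQTest",
  representation(q = "numeric", df = "integer", pval = "numeric")
)

setValidity("MRQTest", function(object) {
  msg <- character(0)
  if (object@q < 0) msg <- c(msg, "Q must be >= 0")
  if (object@df < 1L) msg <- c(msg, "df must be >= 1")
  if (object@pval <= 0 || object@pval > 1) msg <- c(msg, "pval must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' Configuration for the synthetic two-sample cohort generator
#'
#' Defines the data-generating model: independent biallelic SNPs in
#' Hardy-Weinberg proportions, an exposure built additively from genotypes
#' plus normal noise, and a bounded frailty index affected linearly by the
#' exposure, by optional direct (pleiotropic) SNP effects, and by age and sex.
#' Defaults emulate the albumin instrument set: SNP frequencies and exposure
#' effects are those of the bundled fixture, and exposure/FI scales match the
#' source cohort (FI mean about 12%, SD about 7.4%; exposure SD about 0.7 g/L
#' residual so that per-SNP exposure SEs at n = 20,000 match the fixture's).
#'
#' @slot nExposure,nOutcome sample sizes of the two (by default disjoint)
#'   cohorts.
#' @slot snpIds,eaf,bxTrue instrument identifiers, effect-allele frequencies
#'   and true per-allele exposure effects (g/L).
#' @slot thetaTrue true causal effect, FI % per g/L.
#' @slot pleiotropy per-SNP direct effects on the FI (FI % per allele).
#' @slot exposureBase,exposureNoiseSd exposure intercept and residual SD (g/L).
#' @slot fiBaseline,fiNoiseSd FI intercept and residual SD (percentage points).
#' @slot ageMean,ageSd,ageEffect age distribution (years) and its FI effect
#'   (% per year).
#' @slot sexPrevalence probability of being female; `sexEffect` is the FI
#'   difference (%) for women.
#' @slot overlapFraction fraction of the outcome cohort re-used from the
#'   exposure cohort (0 = fully disjoint two-sample design).
#' @slot seed mandatory integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nExposure = "integer", nOutcome = "integer",
    snpIds = "character", eaf = "numeric", bxTrue = "numeric",
    thetaTrue = "numeric", pleiotropy = "numeric",
    exposureBase = "numeric", exposureNoiseSd = "numeric",
    fiBaseline = "numeric", fiNoiseSd = "numeric",
    ageMean = "numeric", ageSd = "numeric", ageEffect = "numeric",
    sexPrevalence = "numeric", sexEffect = "numeric",
    overlapFraction = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  J <- length(object@snpIds)
  if (length(object@eaf) != J || length(object@bxTrue) != J ||
      length(object@pleiotropy) != J)
    msg <- c(msg, "eaf, bxTrue and pleiotropy must have one entry per SNP")
  if (any(object@eaf <= 0 | object@eaf >= 1))
    msg <- c(msg, "effect-allele frequencies must lie in (0,1)")
  if (object@nExposure < 10L || object@nOutcome < 10L)
    msg <- c(msg, "sample sizes must be >= 10")
  if (object@exposureNoiseSd < 0 || object@fiNoiseSd < 0 || object@ageSd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (object@sexPrevalence < 0 || object@sexPrevalence > 1)
    msg <- c(msg, "sexPrevalence must lie in [0,1]")
  if (object@overlapFraction < 0 || object@overlapFraction > 1)
    msg <- c(msg, "overlapFraction must lie in [0,1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "a seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' Individual-level simulated cohort
#'
#' @slot genotypes n x J matrix of effect-allele dosages (0/1/2), SNP ids as
#'   column names.
#' @slot exposure per-individual exposure values (g/L).
#' @slot age,sex covariates (years; 1 = female).
#' @slot fi frailty index in percent, clipped to \[0, 100\].
#' @export
setClass("FrailtyCohort",
  representation(
    genotypes = "matrix", exposure = "numeric",
    age = "numeric", sex = "integer", fi = "numeric"
  )
)

setValidity("FrailtyCohort", function(object) {
  msg <- character(0)
  n <- nrow(object@genotypes)
  if (length(object@exposure) != n || length(object@age) != n ||
      length(object@sex) != n || length(object@fi) != n)
    msg <- c(msg, "cohort fields must all have one entry per individual")
  if (!all(object@genotypes %in% 0:2))
    msg <- c(msg, "genotype dosages must be 0, 1 or 2")
  if (any(object@fi < 0 | object@fi > 100))
    msg <- c(msg, "FI must lie in [0,100]")
  if (any(object@age <= 0)) msg <- c(msg, "age must be > 0")
  if (length(msg)) msg else TRUE
})

#' Full analysis report
#'
#' Produced by [runAnalysis()]: one [MREstimate-class] per successfully run
#' method, instrument-level Cochran's Q, the MR-Lasso selection when
#' requested, soft failures with reasons, and a provenance block.
#'
#' @slot instruments the harmonized, exposure-positive [MRInstrumentSet-class].
#' @slot estimates named list of [MREstimate-class] objects.
#' @slot qtest instrument-level [MRQTest-class], or `NULL` when fewer than
#'   two instruments.
#' @slot lasso [MRLassoFit-class] or `NULL`.
#' @slot failures named character vector: methods that could not run, with
#'   the reason.
#' @slot provenance list: input files, methods requested, seed, options,
#'   package version.
#' @export
setClass("MRAnalysisReport",
  representation(
    instruments = "MRInstrumentSet",
    estimates = "list",
    qtest = "ANY",
    lasso = "ANY",
    failures = "character",
    provenance = "list"
  )
)
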