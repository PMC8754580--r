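# Default instrument panel: frequencies and exposure effects of the bundled
# albumin instrument set.
.DEFAULT_EAF <- c(0.07, 0.61, 0.19, 0.30, 0.04, 0.90)
.DEFAULT_BX  <- c(0.280, 0.153, 0.170, 0.066, 0.215, 0.188)

#' Build a validated simulation configuration
#'
#' Constructs a [SimulationConfig-class] for the synthetic two-sample
#' generator.  Defaults emulate the albumin analysis: the six instrument
#' frequencies/effects of the bundled fixture, an albumin-like exposure
#' (baseline 44.5 g/L, residual SD 0.67 g/L — chosen so per-SNP exposure SEs
#' at n = 20,000 match the fixture's), a causal effect of -0.15 FI% per g/L,
#' no pleiotropy, age ~ N(56.7, 8) years with 0.25 FI%/year, 53.3% women with
#' +1.5 FI%, and an FI residual SD such that the total FI SD is about 7.4%
#' around a mean of about 12%.  When `fiBaseline` is `NA` (default) it is
#' solved so the expected FI equals `fiMean`.
#'
#' @param nExposure,nOutcome cohort sizes (disjoint unless `overlapFraction`
#'   is positive).
#' @param eaf,bxTrue,snpIds instrument panel; equal-length vectors.
#' @param thetaTrue causal effect of the exposure on the FI (% per g/L).
#' @param pleiotropy per-SNP direct effects on the FI (% per allele); scalar
#'   recycled.
#' @param exposureBase,exposureNoiseSd exposure model (g/L).
#' @param fiBaseline,fiNoiseSd,fiMean FI model (percentage points).
#' @param ageMean,ageSd,ageEffect,sexPrevalence,sexEffect covariate model.
#' @param overlapFraction fraction of outcome individuals shared with the
#'   exposure cohort (0 = two-sample design).
#' @param seed mandatory integer seed.
#' @return a [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1, nExposure = 500, nOutcome = 500)
#' @export
simulationConfig <- function(nExposure = 20000, nOutcome = 20000,
                             eaf = .DEFAULT_EAF, bxTrue = .DEFAULT_BX,
                             snpIds = paste0("snp", seq_along(eaf)),
                             thetaTrue = -0.15,
                             pleiotropy = 0,
                             exposureBase = 44.5, exposureNoiseSd = 0.67,
                             fiBaseline = NA_real_, fiNoiseSd = 7.08,
                             fiMean = 12,
                             ageMean = 56.7, ageSd = 8, ageEffect = 0.25,
                             sexPrevalence = 0.533, sexEffect = 1.5,
                             overlapFraction = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  J <- length(eaf)
  if (length(pleiotropy) == 1L) pleiotropy <- rep(pleiotropy, J)
  if (is.na(fiBaseline)) {
    expMean <- exposureBase + sum(bxTrue * 2 * eaf)
    fiBaseline <- fiMean - thetaTrue * expMean - sum(pleiotropy * 2 * eaf) -
      ageEffect * ageMean - sexEffect * sexPrevalence
  }
  new("SimulationConfig",
      nExposure = as.integer(nExposure), nOutcome = as.integer(nOutcome),
      snpIds = snpIds, eaf = eaf, bxTrue = bxTrue,
      thetaTrue = thetaTrue, pleiotropy = pleiotropy,
      exposureBase = exposureBase, exposureNoiseSd = exposureNoiseSd,
      fiBaseline = fiBaseline, fiNoiseSd = fiNoiseSd,
      ageMean = ageMean, ageSd = ageSd, ageEffect = ageEffect,
      sexPrevalence = sexPrevalence, sexEffect = sexEffect,
      overlapFraction = overlapFraction, seed = as.integer(seed))
}

# Draw one cohort from the generative model; assumes the RNG is already
# positioned (no seeding here).
.drawCohort <- function(config, n) {
  J <- length(config@snpIds)
  g <- matrix(rbinom(n * J, 2L, rep(config@eaf, each = n)), nrow = n,
              dimnames = list(NULL, config@snpIds))
  exposure <- config@exposureBase + drop(g %*% config@bxTrue) +
    rnorm(n, 0, config@exposureNoiseSd)
  age <- abs(rnorm(n, config@ageMean, config@ageSd)) + 1e-8
  sex <- rbinom(n, 1L, config@sexPrevalence)
  fiRaw <- config@fiBaseline + config@thetaTrue * exposure +
    drop(g %*% config@pleiotropy) + config@ageEffect * age +
    config@sexEffect * sex + rnorm(n, 0, config@fiNoiseSd)
  new("FrailtyCohort", genotypes = g, exposure = exposure,
      age = age, sex = as.integer(sex), fi = pmin(pmax(fiRaw, 0), 100))
}

#' Simulate an individual-level cohort
#'
#' Genotypes are drawn independently per SNP as Binomial(2, eaf)
#' (Hardy-Weinberg, no linkage disequilibrium); the exposure is the additive
#' genetic score plus normal noise; the frailty index is linear in exposure,
#' direct SNP effects, age and sex plus normal noise, clipped to \[0, 100\].
#' Fully reproducible from the seed.
#'
#' @param config a [SimulationConfig-class].
#' @param n cohort size; defaults to `config`'s outcome-sample size.
#' @param seed RNG seed; defaults to `config`'s.  Applied locally.
#' @return a [FrailtyCohort-class].
#' @examples
#' cohort <- simulateCohort(simulationConfig(seed = 7, nExposure = 200,
#'                                           nOutcome = 200))
#' @export
simulateCohort <- function(config, n = config@nOutcome, seed = config@seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  .drawCohort(config, n)
}

# Per-SNP simple OLS of a quantitative trait on dosage.
.gwasScan <- function(g, y) {
  vapply(seq_len(ncol(g)), function(j) {
    fit <- .ols(cbind(1, g[, j]), y)
    c(beta = unname(fit$beta[2]), se = unname(fit$se[2]),
      pval = unname(fit$pval[2]))
  }, numeric(3))
}

#' Generate two-sample GWAS summary statistics
#'
#' Simulates an exposure cohort and an outcome cohort (disjoint unless the
#' config's `overlapFraction` is positive) from one configuration, then
#' derives summary statistics: per-SNP OLS of the exposure on dosage in the
#' first cohort, and age/sex-adjusted per-SNP FI regressions
#' ([snpFIRegression()]) in the second.  Records use synthetic alleles
#' (effect allele A, other allele G) and the realized sample frequencies.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `exposure` and `outcome`, each a SNP-record
#'   data.frame in the [readSummaryStats()] layout, plus `cohorts` (the two
#'   [FrailtyCohort-class] objects) for inspection.
#' @examples
#' ss <- twoSampleSummary(simulationConfig(seed = 3, nExposure = 1000,
#'                                         nOutcome = 1000))
#' set <- harmonize(ss$exposure, ss$outcome)
#' @export
twoSampleSummary <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config@seed)
  cohortX <- .drawCohort(config, config@nExposure)

  nShared <- floor(config@overlapFraction * min(config@nExposure, config@nOutcome))
  if (nShared > 0) {
    fresh <- .drawCohort(config, config@nOutcome - nShared)
    idx <- seq_len(nShared)
    cohortY <- new("FrailtyCohort",
                   genotypes = rbind(cohortX@genotypes[idx, , drop = FALSE],
                                     fresh@genotypes),
                   exposure = c(cohortX@exposure[idx], fresh@exposure),
                   age = c(cohortX@age[idx], fresh@age),
                   sex = c(cohortX@sex[idx], fresh@sex),
                   fi = c(cohortX@fi[idx], fresh@fi))
  } else {
    cohortY <- .drawCohort(config, config@nOutcome)
  }

  J <- length(config@snpIds)
  scanX <- .gwasScan(cohortX@genotypes, cohortX@exposure)
  outY <- snpFIRegression(cohortY@genotypes, cohortY@fi,
                          data.frame(age = cohortY@age, sex = cohortY@sex))
  record <- function(beta, se, pval, eaf, n) {
    data.frame(snp = config@snpIds, chr = NA_character_,
               effect_allele = "A", other_allele = "G",
               eaf = eaf, beta = beta, se = se, pval = pval, n = n,
               stringsAsFactors = FALSE)
  }
  list(
    exposure = record(scanX["beta", ], scanX["se", ], scanX["pval", ],
                      colMeans(cohortX@genotypes) / 2, config@nExposure),
    outcome = record(outY$beta, outY$se, outY$pval,
                     colMeans(cohortY@genotypes) / 2, config@nOutcome),
    cohorts = list(exposure = cohortX, outcome = cohortY)
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simulationConfig()] in snake_case; the
#' instrument panel is given as a `snps:` list of `{id, eaf, bx}` entries.
#'
#' @param path YAML file.
#' @return a [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  key <- function(from, to) if (!is.null(y[[from]])) args[[to]] <<- y[[from]]
  key("n_exposure", "nExposure"); key("n_outcome", "nOutcome")
  key("theta_true", "thetaTrue"); key("pleiotropy", "pleiotropy")
  key("exposure_base", "exposureBase")
  key("exposure_noise_sd", "exposureNoiseSd")
  key("fi_baseline", "fiBaseline"); key("fi_noise_sd", "fiNoiseSd")
  key("fi_mean", "fiMean")
  key("age_mean", "ageMean"); key("age_sd", "ageSd")
  key("age_effect", "ageEffect")
  key("sex_prevalence", "sexPrevalence"); key("sex_effect", "sexEffect")
  key("overlap_fraction", "overlapFraction"); key("seed", "seed")
  if (!is.null(y$snps)) {
    args$snpIds <- vapply(y$snps, function(s) as.character(s$id), "")
    args$eaf <- vapply(y$snps, function(s) as.numeric(s$eaf), 0)
    args$bxTrue <- vapply(y$snps, function(s) as.numeric(s$bx), 0)
  }
  if (!is.null(args$pleiotropy)) args$pleiotropy <- as.numeric(args$pleiotropy)
  do.call(simulationConfig, args)
}

#' Write an individual-level cohort to delimited text
#'
#' One row per individual: id, per-SNP dosages, exposure, age, sex, FI.
#'
#' @param cohort a [FrailtyCohort-class].
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  df <- data.frame(id = seq_len(nrow(cohort@genotypes)), cohort@genotypes,
                   exposure = cohort@exposure, age = cohort@age,
                   sex = cohort@sex, fi = cohort@fi, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
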