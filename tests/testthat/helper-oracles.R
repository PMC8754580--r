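# Independent oracles and small generators used across the test files.

# Brute-force weighted median: build the piecewise-linear cumulative-weight
# function over midpoint ranks explicitly and invert it numerically at 0.5.
bruteWeightedMedian <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(s)])
  f <- function(t) stats::approx(theta, s, xout = t, ties = "ordered")$y - 0.5
  stats::uniroot(f, range(theta), tol = 1e-12)$root
}

# Random instrument set with exposure-positive orientation.
randomSet <- function(J, seed, theta = 0.3, hetero = 0) {
  set.seed(seed)
  bx <- runif(J, 0.05, 0.5)
  sx <- runif(J, 0.005, 0.02)
  sy <- runif(J, 0.01, 0.05)
  by <- theta * bx + rnorm(J, 0, hetero * sy)
  instrumentSet(paste0("rs", seq_len(J)), bx, sx, by, sy)
}

# Deterministic toy records in the standard summary-stat layout.
toyRecords <- function(snp, ea, oa, beta, se, eaf = NA_real_) {
  data.frame(snp = snp, chr = "1", effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, pval = 0.5, n = 1000,
             stringsAsFactors = FALSE)
}

writeTempStats <- function(records) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeSummaryStats(records, path)
  path
}

# Split the bundled fixture files by trait into temporary one-trait files.
fixtureFiles <- function(trait, envir = parent.frame()) {
  dir <- system.file("extdata", package = "frailMR")
  out <- lapply(c(exposure = "table1_exposure.tsv",
                  outcome = "table1_outcome.tsv"), function(f) {
    tab <- utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE)
    tab <- tab[tab$trait == trait, setdiff(names(tab), "trait")]
    path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
    writeSummaryStats(tab, path)
    path
  })
  out
}
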