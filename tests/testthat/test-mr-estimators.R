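test_that("ratio estimates follow the Wald formula and its homogeneity", {
  tp <- table1Fixture("total_protein")
  r <- ratioEstimates(tp)
  i <- match("rs204999", r$snp)
  expect_equal(r$theta[i], -0.058 / 0.250)
  expect_equal(r$theta[i], -0.232, tolerance = 1e-12)
  expect_equal(r$w[i], 0.250^2 / 0.019^2)
  expect_equal(r$w[i], 173.130, tolerance = 1e-5)
  expect_equal(r$se[i], 0.019 / 0.250)

  # by = 0 gives a zero ratio regardless of bx
  set0 <- instrumentSet("rs1", bx = 0.4, sx = 0.01, by = 0, sy = 0.02)
  expect_equal(ratioEstimates(set0)$theta, 0)

  # scaling (by, sy) by c scales se by c and leaves theta unchanged
  k <- 3.7
  scaled <- instrumentSet(snps(tp), exposureBeta(tp), exposureSE(tp),
                          k * outcomeBeta(tp), k * outcomeSE(tp))
  rs <- ratioEstimates(scaled)
  expect_equal(rs$theta, k * r$theta)        # numerator scaling
  expect_equal(rs$se, k * r$se)
  same <- instrumentSet(snps(tp), exposureBeta(tp), exposureSE(tp),
                        outcomeBeta(tp), k * outcomeSE(tp))
  expect_equal(ratioEstimates(same)$theta, r$theta)

  # zero exposure effect is a degenerate instrument
  bad <- instrumentSet(c("rs1", "rsZ"), bx = c(0.2, 0), sx = c(0.01, 0.01),
                       by = c(0.1, 0.1), sy = c(0.02, 0.02))
  expect_error(ratioEstimates(bad), "rsZ")
})

test_that("fixed-effect IVW equals origin-constrained WLS and behaves at edges", {
  # oracle equivalence on random instances
  for (seed in 1:5) {
    set <- randomSet(6, seed, hetero = 2)
    fit <- mrIVW(set)
    oracle <- lm(set@by ~ set@bx - 1, weights = 1 / set@sy^2)
    expect_equal(estimate(fit), unname(coef(oracle)), tolerance = 1e-12)
    # fixed-effect SE = model SE divided by the residual scale
    sigma <- summary(oracle)$sigma
    expect_equal(stdError(fit),
                 unname(coef(summary(oracle))[, 2]) / sigma, tolerance = 1e-10)
  }

  # single instrument reduces to the ratio estimate
  one <- instrumentSet("rs1", bx = 0.25, sx = 0.011, by = -0.058, sy = 0.019)
  fit1 <- mrIVW(one)
  expect_equal(estimate(fit1), -0.232)
  expect_equal(stdError(fit1), 0.019 / 0.25)

  # exact proportionality: point estimate recovered, Q = 0
  exact <- instrumentSet(paste0("rs", 1:3), bx = c(0.1, 0.2, 0.3),
                         sx = rep(0.01, 3), by = 0.5 * c(0.1, 0.2, 0.3),
                         sy = c(0.02, 0.03, 0.04))
  expect_equal(estimate(mrIVW(exact)), 0.5, tolerance = 1e-12)
  expect_equal(qStatistic(cochranQ(exact)), 0, tolerance = 1e-20)

  # CI slots honour the normal-quantile contract
  expect_equal(ciLower(fit1), estimate(fit1) - 1.959964 * stdError(fit1))
  expect_equal(ciUpper(fit1), estimate(fit1) + 1.959964 * stdError(fit1))
})

test_that("estimators are invariant to reordering and joint per-SNP sign flips", {
  set <- randomSet(7, 11, hetero = 1.5)
  perm <- set[c(4, 1, 7, 3, 6, 2, 5)]
  flip <- c(2, 5)  # flip (bx, by) jointly for two SNPs
  sgn <- ifelse(seq_len(7) %in% flip, -1, 1)
  flipped <- instrumentSet(snps(set), sgn * set@bx, set@sx,
                           sgn * set@by, set@sy)
  for (f in list(mrIVW, mrPenalizedIVW,
                 function(s) mrWeightedMedian(s, nBoot = 50, seed = 1))) {
    expect_equal(estimate(f(set)), estimate(f(perm)), tolerance = 1e-12)
    expect_equal(estimate(f(set)), estimate(f(flipped)), tolerance = 1e-12)
  }
  expect_equal(validSNPs(mrLasso(set)), validSNPs(mrLasso(flipped)))
  # Egger is invariant once the orientation convention is re-applied
  expect_equal(estimate(mrEgger(orientPositiveExposure(flipped))),
               estimate(mrEgger(set)), tolerance = 1e-12)
})

test_that("penalized IVW reduces to IVW without outliers and crushes planted ones", {
  # homogeneous set: all chi-squared(1) tail probabilities >= 1/20
  calm <- randomSet(6, 3, hetero = 0.5)
  r <- ratioEstimates(calm)
  th <- sum(r$w * r$theta) / sum(r$w)
  if (min(pchisq(r$w * (r$theta - th)^2, 1, lower.tail = FALSE)) >= 0.05) {
    expect_equal(estimate(mrPenalizedIVW(calm)), estimate(mrIVW(calm)),
                 tolerance = 1e-12)
    expect_equal(stdError(mrPenalizedIVW(calm)), stdError(mrIVW(calm)),
                 tolerance = 1e-12)
  }

  # a ratio estimate 10 SEs out keeps < 5% of its weight
  bx <- c(0.2, 0.25, 0.3, 0.22, 0.28, 0.26)
  sy <- rep(0.02, 6)
  by <- 0.4 * bx
  by[4] <- 0.4 * bx[4] + 10 * sy[4]
  planted <- instrumentSet(paste0("rs", 1:6), bx, rep(0.01, 6), by, sy)
  fit <- mrPenalizedIVW(planted)
  pf <- extras(fit)$penaltyFactor
  expect_lt(pf[["rs4"]], 0.05)
  expect_true(all(pf[setdiff(names(pf), "rs4")] > 0.5))

  # on the bundled albumin set only rs1260326 is down-weighted
  alb <- mrPenalizedIVW(table1Fixture("albumin"))
  pf <- extras(alb)$penaltyFactor
  expect_lt(pf[["rs1260326"]], 1)
  expect_equal(unname(pf[setdiff(names(pf), "rs1260326")]), rep(1, 5))
  expect_lt(abs(estimate(alb) - (-0.120)), 0.03)

  expect_error(mrPenalizedIVW(planted[1]), "at least 2")
})

test_that("weighted median reduces to the middle ratio and matches brute force", {
  # three equally weighted instruments -> middle ratio estimate
  eq <- instrumentSet(paste0("rs", 1:3), bx = c(0.2, 0.2, 0.2),
                      sx = rep(0.01, 3), by = c(0.02, 0.08, 0.05),
                      sy = rep(0.02, 3))
  fit <- mrWeightedMedian(eq, nBoot = 50, seed = 1)
  expect_equal(estimate(fit), 0.05 / 0.2)

  # equal weights equal the unweighted midpoint-interpolated median
  r <- ratioEstimates(eq)
  expect_equal(estimate(fit), bruteWeightedMedian(r$theta, rep(1, 3)))

  # brute-force oracle on random 5-instrument sets
  for (seed in 21:25) {
    set <- randomSet(5, seed, hetero = 3)
    r <- ratioEstimates(set)
    expect_equal(estimate(mrWeightedMedian(set, nBoot = 50, seed = 1)),
                 bruteWeightedMedian(r$theta, r$w), tolerance = 1e-9)
  }

  # the point estimate is deterministic, the bootstrap SE seed-reproducible
  alb <- table1Fixture("albumin")
  a <- mrWeightedMedian(alb, nBoot = 200, seed = 7)
  b <- mrWeightedMedian(alb, nBoot = 200, seed = 7)
  c <- mrWeightedMedian(alb, nBoot = 200, seed = 8)
  expect_identical(estimate(a), estimate(b))
  expect_identical(stdError(a), stdError(b))
  expect_identical(estimate(a), estimate(c))
  expect_false(identical(stdError(a), stdError(c)))

  expect_error(mrWeightedMedian(eq[1:2]), "at least 3")
})

test_that("Egger recovers exact linear data and matches the WLS oracle", {
  # exact generative line: intercept and slope to machine precision
  bx <- c(0.1, 0.15, 0.22, 0.3, 0.05)
  sy <- c(0.02, 0.03, 0.025, 0.04, 0.02)
  exact <- instrumentSet(paste0("rs", 1:5), bx, rep(0.01, 5),
                         by = 0.02 + 0.4 * bx, sy = sy)
  fit <- mrEgger(exact)
  expect_equal(estimate(fit), 0.4, tolerance = 1e-12)
  expect_equal(extras(fit)$intercept, 0.02, tolerance = 1e-12)
  expect_equal(extras(fit)$dispersion, 1)

  # generic WLS oracle on random instances, both dispersion conventions
  for (seed in 31:34) {
    set <- randomSet(6, seed, hetero = 2)
    oracle <- lm(set@by ~ set@bx, weights = 1 / set@sy^2)
    co <- coef(summary(oracle))
    fitM <- mrEgger(set)
    fitF <- mrEgger(set, dispersion = "fixed")
    expect_equal(estimate(fitM), unname(co[2, 1]), tolerance = 1e-10)
    expect_equal(extras(fitM)$intercept, unname(co[1, 1]), tolerance = 1e-10)
    sigma <- summary(oracle)$sigma  # sqrt(Q_E/(J-2)) in the weighted metric
    expect_equal(stdError(fitF), unname(co[2, 2]) / sigma, tolerance = 1e-10)
    expect_equal(stdError(fitM), unname(co[2, 2]) / sigma * max(1, sigma),
                 tolerance = 1e-10)
    expect_equal(extras(fitM)$qE, sum(residuals(oracle)^2 / set@sy^2),
                 tolerance = 1e-10)
  }

  expect_error(mrEgger(exact[1:2]), "at least 3")
  same <- instrumentSet(paste0("rs", 1:3), bx = rep(0.2, 3), sx = rep(0.01, 3),
                        by = c(0.1, 0.12, 0.08), sy = rep(0.02, 3))
  expect_error(mrEgger(same), "singular")
  neg <- instrumentSet(paste0("rs", 1:3), bx = c(-0.1, 0.2, 0.3),
                       sx = rep(0.01, 3), by = c(0.1, 0.1, 0.1),
                       sy = rep(0.02, 3))
  expect_error(mrEgger(neg), "orientation")
})

test_that("MR-Lasso keeps everything under a dominating penalty and flags planted
           pleiotropy", {
  set <- randomSet(6, 41, hetero = 1)
  # penalty-dominated limit: single huge lambda -> all alphas zero, IVW back
  fit <- mrLasso(set, lambdaGrid = 1e8)
  expect_equal(unname(alphas(fit)), rep(0, 6))
  expect_setequal(validSNPs(fit), snps(set))
  expect_equal(estimate(estimate(fit)), estimate(mrIVW(set)), tolerance = 1e-12)

  # partition invariant
  expect_setequal(c(validSNPs(fit), invalidSNPs(fit)), snps(set))

  # planted direct effect of 5 outcome-SEs on one SNP, small noise elsewhere
  set.seed(99)
  bx <- c(0.28, 0.15, 0.17, 0.07, 0.21, 0.19)
  sy <- rep(0.02, 6)
  theta <- -0.15
  by <- theta * bx + rnorm(6, 0, sy)
  by[3] <- by[3] + 5 * sy[3]
  planted <- instrumentSet(paste0("rs", 1:6), bx, rep(0.01, 6), by, sy)
  pfit <- mrLasso(planted)
  expect_identical(invalidSNPs(pfit), "rs3")
  post <- estimate(pfit)
  expect_lt(abs(estimate(post) - theta), 2 * stdError(post))
  expect_gt(nrow(selectionPath(pfit)), 1L)

  # exact-fit degenerate case: lambda_max = 0, everything valid
  exact <- instrumentSet(paste0("rs", 1:3), bx = c(0.1, 0.2, 0.3),
                         sx = rep(0.01, 3), by = 0.5 * c(0.1, 0.2, 0.3),
                         sy = rep(0.02, 3))
  efit <- mrLasso(exact)
  expect_equal(length(validSNPs(efit)), 3L)

  expect_error(mrLasso(exact[1:2]), "at least 3")
})
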