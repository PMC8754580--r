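test_that("reading the bundled exposure table yields validated records", {
  path <- system.file("extdata", "table1_exposure.tsv", package = "frailMR")
  rec <- readSummaryStats(path)
  expect_equal(nrow(rec), 8L)
  alb <- rec[rec$snp %in% c("rs4806073", "rs1260326", "rs11078597",
                            "rs13381710", "rs16948098", "rs739347"), ]
  expect_equal(nrow(alb), 6L)
  r <- rec[rec$snp == "rs4806073", ]
  expect_equal(r$beta, 0.280)
  expect_equal(r$se, 0.013)
  expect_equal(r$effect_allele, "C")
  expect_equal(r$eaf, 0.07)
})

test_that("reader handles empty tables, rejects bad rows, errors on bad input", {
  # header only -> empty collection
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("snp\tchr\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn", empty)
  expect_equal(nrow(readSummaryStats(empty)), 0L)

  # se = 0 row dropped with a row-indexed diagnostic
  rec <- toyRecords(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                    beta = c(0.1, 0.2), se = c(0.01, 0))
  path <- writeTempStats(rec)
  expect_warning(kept <- readSummaryStats(path), "row 2.*SE not > 0")
  expect_equal(kept$snp, "rs1")

  # missing mandatory column -> configuration error
  broken <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tbeta\tse", "rs1\t0.1\t0.01"), broken)
  expect_error(readSummaryStats(broken), "mandatory column")

  # non-numeric beta -> parse error naming the row
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\teffect_allele\tother_allele\tbeta\tse",
               "rs1\tA\tG\t0.1\t0.01", "rs2\tA\tG\txx\t0.01"), bad)
  expect_error(readSummaryStats(bad), "non-numeric.*beta.*row\\(s\\) 2")

  # column mapping resolves non-default headers
  mapped <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tEA\tOA\tb\tstderr", "rs9\tA\tG\t0.3\t0.05"), mapped)
  rec <- readSummaryStats(mapped, columnMap = c(snp = "rsid",
                                                effect_allele = "EA",
                                                other_allele = "OA",
                                                beta = "b", se = "stderr"))
  expect_equal(rec$snp, "rs9")
  expect_equal(rec$beta, 0.3)
})

test_that("write/read round trip reproduces all fields", {
  rec <- toyRecords(c("rs1", "rs2", "rs3"), c("A", "C", "T"), c("G", "T", "A"),
                    beta = c(0.123, -0.456, 0.007), se = c(0.01, 0.002, 0.5),
                    eaf = c(0.25, NA, 0.9))
  rec$pval <- c(1e-12, 0.05, 1)
  path <- writeTempStats(rec)
  back <- readSummaryStats(path)
  expect_equal(back, rec)
})

test_that("harmonize pairs, flips and drops SNPs by allele configuration", {
  exposure <- toyRecords(c("rs1", "rs2", "rs3", "rs4"),
                         ea = c("C", "C", "A", "C"), oa = c("T", "T", "G", "T"),
                         beta = c(0.28, 0.10, 0.20, 0.15),
                         se = c(0.013, 0.01, 0.01, 0.01),
                         eaf = c(0.07, 0.30, 0.40, 0.20))
  # rs4's alleles (A/C) share no valid configuration with the exposure's C/T,
  # not even after strand complement
  outcome <- toyRecords(c("rs1", "rs2", "rs3", "rs4", "rs9"),
                        ea = c("C", "T", "A", "A", "A"),
                        oa = c("T", "C", "G", "C", "G"),
                        beta = c(-0.006, 0.006, 0.05, 0.02, 0.1),
                        se = c(0.034, 0.02, 0.02, 0.02, 0.02),
                        eaf = c(0.07, 0.70, 0.40, 0.20, 0.5))
  # rs1 identical alleles; rs2 swapped (sign flip); rs3 identical;
  # rs4 allele mismatch (C/T vs A/G) -> dropped; rs9 absent from exposure
  expect_warning(set <- harmonize(exposure, outcome), "rs4")
  expect_setequal(snps(set), c("rs1", "rs2", "rs3"))
  expect_equal(unname(outcomeBeta(set)[match("rs1", snps(set))]), -0.006)
  expect_equal(unname(outcomeBeta(set)[match("rs2", snps(set))]), -0.006)

  # strand-complement pairing: exposure C/T vs outcome G/A (same orientation)
  out2 <- toyRecords("rs1", ea = "G", oa = "A", beta = -0.006, se = 0.034,
                     eaf = 0.07)
  set2 <- harmonize(exposure[1, ], out2)
  expect_equal(unname(outcomeBeta(set2)), -0.006)

  # zero overlap -> error
  expect_error(harmonize(exposure, toyRecords("rs99", "A", "G", 0.1, 0.01)),
               "no overlapping SNPs")
})

test_that("palindromic SNPs are dropped when ambiguous, resolved by frequency", {
  exposure <- toyRecords(c("rs1", "rs2"), ea = c("A", "A"), oa = c("T", "T"),
                         beta = c(0.2, 0.2), se = c(0.01, 0.01),
                         eaf = c(0.50, 0.10))
  outcome <- toyRecords(c("rs1", "rs2"), ea = c("A", "A"), oa = c("T", "T"),
                        beta = c(0.05, 0.05), se = c(0.02, 0.02),
                        eaf = c(0.50, 0.85))
  # rs1: both frequencies mid-range -> dropped with warning
  # rs2: exposure eaf 0.10 vs outcome 0.85 -> opposite strand, flip
  expect_warning(set <- harmonize(exposure, outcome), "palindromic")
  expect_equal(snps(set), "rs2")
  expect_equal(unname(outcomeBeta(set)), -0.05)

  # missing frequency on a palindromic SNP is also unresolvable
  out_na <- toyRecords("rs1", "A", "T", 0.05, 0.02, eaf = NA_real_)
  expect_warning(expect_error(harmonize(exposure[1, ], out_na),
                              "no instruments survived"),
                 "palindromic")

  # frequency agreement keeps the orientation
  out_agree <- toyRecords("rs2", "A", "T", 0.05, 0.02, eaf = 0.12)
  set3 <- harmonize(exposure[2, ], out_agree)
  expect_equal(unname(outcomeBeta(set3)), 0.05)
})

test_that("harmonize is invariant to wholesale outcome re-orientation", {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  exposure <- toyRecords(c("rs1", "rs2", "rs3"), ea = c("C", "T", "A"),
                         oa = c("T", "G", "C"), beta = c(0.28, 0.15, 0.07),
                         se = c(0.013, 0.01, 0.008), eaf = c(0.07, 0.61, 0.25))
  outcome <- toyRecords(c("rs1", "rs2", "rs3"), ea = c("C", "T", "A"),
                        oa = c("T", "G", "C"), beta = c(-0.006, 0.04, -0.01),
                        se = c(0.034, 0.018, 0.02), eaf = c(0.07, 0.61, 0.25))
  flipped <- outcome
  flipped$effect_allele <- outcome$other_allele
  flipped$other_allele <- outcome$effect_allele
  flipped$beta <- -outcome$beta
  flipped$eaf <- 1 - outcome$eaf
  a <- harmonize(exposure, outcome)
  b <- harmonize(exposure, flipped)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("orientPositiveExposure flips jointly, is idempotent, IVW-invariant", {
  set <- instrumentSet(c("rs1", "rs2"), bx = c(-0.1, 0.2), sx = c(0.01, 0.01),
                       by = c(0.05, 0.1), sy = c(0.02, 0.02),
                       eafX = c(0.3, 0.4))
  flipped <- orientPositiveExposure(set)
  expect_equal(unname(exposureBeta(flipped)), c(0.1, 0.2))
  expect_equal(unname(outcomeBeta(flipped)), c(-0.05, 0.1))
  expect_equal(flipped@eafX, c(0.7, 0.4))
  expect_equal(as.data.frame(orientPositiveExposure(flipped)),
               as.data.frame(flipped))
  expect_equal(estimate(mrIVW(set)), estimate(mrIVW(flipped)))
  # the bundled albumin set is already exposure-positive
  alb <- table1Fixture("albumin")
  expect_equal(as.data.frame(orientPositiveExposure(alb)), as.data.frame(alb))
})

test_that("bundled fixture matches the tabulated instrument sets exactly", {
  alb <- table1Fixture("albumin")
  expect_equal(length(alb), 6L)
  expect_equal(snps(alb), c("rs4806073", "rs1260326", "rs11078597",
                            "rs13381710", "rs16948098", "rs739347"))
  expect_equal(unname(exposureBeta(alb)),
               c(0.280, 0.153, 0.170, 0.066, 0.215, 0.188))
  expect_equal(unname(exposureSE(alb)),
               c(0.013, 0.007, 0.008, 0.007, 0.016, 0.011))
  expect_equal(unname(outcomeBeta(alb)),
               c(-0.006, 0.040, -0.007, -0.020, -0.082, -0.042))
  expect_equal(unname(outcomeSE(alb)),
               c(0.034, 0.018, 0.022, 0.019, 0.043, 0.029))
  expect_equal(alb@eafX, c(0.07, 0.61, 0.19, 0.30, 0.04, 0.90))

  tp <- table1Fixture("total_protein")
  expect_equal(length(tp), 2L)
  expect_equal(unname(exposureBeta(tp)["rs204999"]), 0.250)
  expect_equal(unname(exposureSE(tp)["rs204999"]), 0.011)
  expect_equal(unname(outcomeBeta(tp)["rs3751991"]), -0.038)
  expect_equal(unname(outcomeSE(tp)["rs3751991"]), 0.029)
  expect_error(table1Fixture("lipids"))
})

test_that("instrument-set validity catches malformed inputs", {
  expect_error(instrumentSet(c("rs1", "rs1"), c(0.1, 0.2), c(0.01, 0.01),
                             c(0.1, 0.1), c(0.01, 0.01)), "unique")
  expect_error(instrumentSet("rs1", 0.1, 0, 0.1, 0.01), "SEs")
  expect_error(instrumentSet(character(0), numeric(0), numeric(0),
                             numeric(0), numeric(0)), "at least 1")
})
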