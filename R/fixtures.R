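#' Bundled instrument sets of the motivating study
#'
#' Returns the harmonized instrument set for one of the two serum-protein
#' exposures exactly as tabulated in the study the package reproduces:
#' 6 SNPs for serum albumin, 2 SNPs for serum total protein.  Exposure betas
#' and SEs are in g/L per effect allele (full-sample GWAS, n = 315,268);
#' outcome betas and SEs are frailty-index percentage points per allele from
#' age- and sex-adjusted regressions (n = 356,432).  Both sides are already
#' expressed on the same effect allele, with all exposure effects positive
#' (protein-raising alleles).
#'
#' The underlying delimited files ship in `inst/extdata/` as
#' `table1_exposure.tsv` and `table1_outcome.tsv` (columns of
#' [defaultColumnMap()] plus a `trait` column).
#'
#' @param trait `"albumin"` or `"total_protein"`.
#' @return an [MRInstrumentSet-class].
#' @examples
#' table1Fixture("albumin")
#' length(table1Fixture("total_protein"))  # 2
#' @export
table1Fixture <- function(trait = c("albumin", "total_protein")) {
  trait <- match.arg(trait)
  dir <- system.file("extdata", package = "frailMR", mustWork = TRUE)
  keepTrait <- function(path) {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE)
    ids <- raw$snp[raw$trait == trait]
    rec <- readSummaryStats(path)
    rec[rec$snp %in% ids, , drop = FALSE]
  }
  exposure <- keepTrait(file.path(dir, "table1_exposure.tsv"))
  outcome <- keepTrait(file.path(dir, "table1_outcome.tsv"))
  label <- c(albumin = "serum albumin", total_protein = "serum total protein")
  harmonize(exposure, outcome, exposureName = label[[trait]],
            outcomeName = "frailty index")
}
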