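#' Default column names for GWAS summary-statistic tables
#'
#' Standard field -> column-name mapping used by [readSummaryStats()] and
#' [writeSummaryStats()].  Mandatory fields are `snp`, `effect_allele`,
#' `other_allele`, `beta` and `se`; `chr`, `eaf`, `pval` and `n` are optional.
#'
#' @return named character vector.
#' @export
defaultColumnMap <- function() {
  c(snp = "snp", chr = "chr", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "eaf", beta = "beta",
    se = "se", pval = "pval", n = "n")
}

.MANDATORY <- c("snp", "effect_allele", "other_allele", "beta", "se")

# Coerce a raw column to numeric; error (naming rows) on unparseable entries.
.numericColumn <- function(x, field, allow_na = TRUE) {
  raw <- as.character(x)
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) & !(is.na(raw) | raw == "" | raw == "NA"))
  if (length(bad))
    stop(sprintf("non-numeric value for '%s' in row(s) %s", field,
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (!allow_na && anyNA(out))
    stop(sprintf("missing value for mandatory field '%s'", field), call. = FALSE)
  out
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table with a header row (the delimiter is
#' sniffed from the header) into a SNP-record data frame with standardized
#' columns `snp, chr, effect_allele, other_allele, eaf, beta, se, pval, n`.
#' Rows violating the record invariants (non-positive SE, malformed alleles,
#' identical alleles, frequency or p-value out of range) are dropped with a
#' row-indexed warning; unparseable numeric fields raise an error naming the
#' row.  Missing values may be encoded as empty strings or `"NA"`.
#'
#' @param path path to the file.
#' @param columnMap named character vector mapping the standard field names
#'   to the file's column names; defaults to [defaultColumnMap()].  Only
#'   entries that differ from the default need to be supplied.
#' @return `data.frame` with one validated SNP record per row and the
#'   standardized columns above (missing optional columns are `NA`).
#' @examples
#' path <- system.file("extdata", "table1_exposure.tsv", package = "frailMR")
#' head(readSummaryStats(path))
#' @export
readSummaryStats <- function(path, columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cmap <- defaultColumnMap()
  if (!is.null(columnMap)) {
    if (is.null(names(columnMap)) || any(!names(columnMap) %in% names(cmap)))
      stop("columnMap must be named by standard fields: ",
           paste(names(cmap), collapse = ", "), call. = FALSE)
    cmap[names(columnMap)] <- columnMap
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = c("", "NA"),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  missing_cols <- setdiff(cmap[.MANDATORY], names(raw))
  if (length(missing_cols))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  pick <- function(field) {
    col <- cmap[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  rec <- data.frame(
    snp = as.character(pick("snp")),
    chr = as.character(pick("chr")),
    effect_allele = toupper(as.character(pick("effect_allele"))),
    other_allele = toupper(as.character(pick("other_allele"))),
    eaf = .numericColumn(pick("eaf"), "eaf"),
    beta = .numericColumn(pick("beta"), "beta", allow_na = FALSE),
    se = .numericColumn(pick("se"), "se", allow_na = FALSE),
    pval = .numericColumn(pick("pval"), "pval"),
    n = .numericColumn(pick("n"), "n"),
    stringsAsFactors = FALSE
  )
  validateSNPRecords(rec)
}

#' Validate SNP records, dropping offending rows with diagnostics
#'
#' Enforces the record invariants: `se > 0`, uppercase single-nucleotide
#' alleles with `effect_allele != other_allele`, `eaf` in (0,1) when present,
#' `pval` in (0,1] when present, non-missing `snp` and `beta`.
#'
#' @param records data.frame with the standardized columns of
#'   [readSummaryStats()].
#' @return the records that pass, with row names reset.  Failing rows are
#'   dropped with a single warning listing row indices and reasons.
#' @export
validateSNPRecords <- function(records) {
  nuc <- c("A", "C", "G", "T")
  reasons <- vector("list", nrow(records))
  flag <- function(cond, why) {
    for (i in which(cond)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  flag(is.na(records$snp) | records$snp == "", "missing SNP id")
  flag(is.na(records$beta), "missing beta")
  flag(is.na(records$se) | records$se <= 0, "SE not > 0")
  flag(!(records$effect_allele %in% nuc), "effect allele not a single base")
  flag(!(records$other_allele %in% nuc), "other allele not a single base")
  flag(!is.na(records$effect_allele) & !is.na(records$other_allele) &
         records$effect_allele == records$other_allele, "identical alleles")
  flag(!is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1),
       "eaf outside (0,1)")
  flag(!is.na(records$pval) & (records$pval <= 0 | records$pval > 1),
       "pval outside (0,1]")
  bad <- which(lengths(reasons) > 0)
  if (length(bad)) {
    warning(sprintf("dropping %d invalid row(s): %s", length(bad),
                    paste(sprintf("row %d (%s)", bad,
                                  vapply(reasons[bad], paste, "",
                                         collapse = "; ")),
                          collapse = ", ")), call. = FALSE)
    records <- records[-bad, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Write SNP records to a delimited text file
#'
#' Inverse of [readSummaryStats()]: writes the standardized columns as
#' tab-separated text with header, missing values as `"NA"`.  A write/read
#' round trip reproduces all fields.
#'
#' @param records SNP-record data.frame.
#' @param path output path.
#' @param sep field separator, tab by default.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(records, path, sep = "\t") {
  cols <- names(defaultColumnMap())
  for (col in setdiff(cols, names(records))) records[[col]] <- NA
  utils::write.table(format(records[cols], digits = 15, trim = TRUE,
                            scientific = NA),
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct an instrument set directly from paired effect vectors
#'
#' Low-level constructor used by [harmonize()] and convenient for synthetic
#' examples and tests.
#'
#' @param snps SNP identifiers.
#' @param bx,sx exposure betas and SEs.
#' @param by,sy outcome betas and SEs.
#' @param eafX optional exposure-side effect-allele frequencies.
#' @param exposureName,outcomeName trait labels.
#' @return an [MRInstrumentSet-class].
#' @examples
#' instrumentSet(c("rs1", "rs2", "rs3"), bx = c(0.1, 0.2, 0.3),
#'               sx = c(0.01, 0.01, 0.01), by = c(0.05, 0.1, 0.15),
#'               sy = c(0.02, 0.02, 0.02))
#' @export
instrumentSet <- function(snps, bx, sx, by, sy, eafX = rep(NA_real_, length(snps)),
                          exposureName = "exposure", outcomeName = "outcome") {
  new("MRInstrumentSet", exposureName = exposureName, outcomeName = outcomeName,
      snps = as.character(snps), bx = as.numeric(bx), sx = as.numeric(sx),
      by = as.numeric(by), sy = as.numeric(sy), eafX = as.numeric(eafX))
}
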