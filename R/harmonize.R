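.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.isPalindromic <- function(ea, oa) .COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' Pairs exposure and outcome records by SNP identifier (intersection join)
#' and orients the outcome effect to the exposure's effect allele:
#'
#' * identical alleles (directly or after strand complement): kept as is;
#' * swapped alleles (directly or after strand complement): outcome beta
#'   sign-flipped, outcome eaf replaced by `1 - eaf`;
#' * any other allele combination: SNP dropped with a warning;
#' * palindromic SNPs (A/T or C/G): undecidable from allele labels, so they
#'   are resolved by effect-allele frequency agreement; when either frequency
#'   is missing or both lie inside the ambiguity window (minor-allele
#'   frequency too close to 0.5), the SNP is dropped with a warning.
#'
#' @param exposure,outcome SNP-record data.frames from [readSummaryStats()].
#' @param exposureName,outcomeName trait labels carried into the result.
#' @param palindromicWindow frequency window treated as strand-ambiguous for
#'   palindromic SNPs; default `c(0.42, 0.58)`.
#' @return an [MRInstrumentSet-class] of the harmonized instruments.
#' @examples
#' path <- system.file("extdata", package = "frailMR")
#' exp <- readSummaryStats(file.path(path, "table1_exposure.tsv"))
#' out <- readSummaryStats(file.path(path, "table1_outcome.tsv"))
#' alb <- exp$snp[1:6]  # albumin block
#' harmonize(exp[exp$snp %in% alb, ], out[out$snp %in% alb, ],
#'           exposureName = "serum albumin", outcomeName = "frailty index")
#' @export
harmonize <- function(exposure, outcome,
                      exposureName = "exposure", outcomeName = "outcome",
                      palindromicWindow = c(0.42, 0.58)) {
  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared))
    stop("no overlapping SNPs between exposure and outcome", call. = FALSE)
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]

  keep <- logical(length(shared))
  by <- numeric(length(shared)); eafY <- rep(NA_real_, length(shared))
  dropped <- character(0)

  for (i in seq_along(shared)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- .isPalindromic(ea_x, oa_x)

    if (pal) {
      # allele labels cannot identify the strand; use frequency agreement
      fx <- ex$eaf[i]; fy <- ou$eaf[i]
      same_pair <- (ea_y == ea_x && oa_y == oa_x) ||
                   (ea_y == oa_x && oa_y == ea_x)
      if (!same_pair) {
        dropped <- c(dropped, sprintf("%s (allele mismatch)", shared[i]))
        next
      }
      ambiguous <- is.na(fx) || is.na(fy) ||
        (fx >= palindromicWindow[1] && fx <= palindromicWindow[2] &&
         fy >= palindromicWindow[1] && fy <= palindromicWindow[2])
      if (ambiguous) {
        dropped <- c(dropped, sprintf("%s (palindromic, ambiguous frequency)",
                                      shared[i]))
        next
      }
      aligned_freq <- if (ea_y == ea_x) fy else 1 - fy
      if ((fx < 0.5) == (aligned_freq < 0.5)) {
        by[i] <- if (ea_y == ea_x) ou$beta[i] else -ou$beta[i]
        eafY[i] <- aligned_freq
      } else {
        by[i] <- if (ea_y == ea_x) -ou$beta[i] else ou$beta[i]
        eafY[i] <- 1 - aligned_freq
      }
      keep[i] <- TRUE
      next
    }

    if (ea_y == ea_x && oa_y == oa_x) {            # identical
      by[i] <- ou$beta[i]; eafY[i] <- ou$eaf[i]
    } else if (ea_y == oa_x && oa_y == ea_x) {     # swapped
      by[i] <- -ou$beta[i]
      eafY[i] <- if (is.na(ou$eaf[i])) NA_real_ else 1 - ou$eaf[i]
    } else if (.COMPLEMENT[ea_y] == ea_x && .COMPLEMENT[oa_y] == oa_x) {
      by[i] <- ou$beta[i]; eafY[i] <- ou$eaf[i]    # other strand, same order
    } else if (.COMPLEMENT[ea_y] == oa_x && .COMPLEMENT[oa_y] == ea_x) {
      by[i] <- -ou$beta[i]                         # other strand, swapped
      eafY[i] <- if (is.na(ou$eaf[i])) NA_real_ else 1 - ou$eaf[i]
    } else {
      dropped <- c(dropped, sprintf("%s (allele mismatch)", shared[i]))
      next
    }
    keep[i] <- TRUE
  }

  if (length(dropped))
    warning("dropped during harmonization: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  if (!any(keep))
    stop("no instruments survived harmonization", call. = FALSE)

  instrumentSet(shared[keep], bx = ex$beta[keep], sx = ex$se[keep],
                by = by[keep], sy = ou$se[keep], eafX = ex$eaf[keep],
                exposureName = exposureName, outcomeName = outcomeName)
}

#' Orient an instrument set so all exposure effects are non-negative
#'
#' Jointly sign-flips (`bx`, `by`) for instruments with negative exposure
#' beta (the effect-allele frequency is complemented accordingly).  This is
#' the standard precondition for MR-Egger; the IVW, weighted-median and lasso
#' estimates are invariant under it.  Idempotent.
#'
#' @param set an [MRInstrumentSet-class].
#' @return the re-oriented [MRInstrumentSet-class].
#' @export
orientPositiveExposure <- function(set) {
  flip <- set@bx < 0
  if (!any(flip)) return(set)
  initialize(set,
             bx = ifelse(flip, -set@bx, set@bx),
             by = ifelse(flip, -set@by, set@by),
             eafX = ifelse(flip & !is.na(set@eafX), 1 - set@eafX, set@eafX))
}
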