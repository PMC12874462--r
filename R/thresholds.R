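#' Survey decision thresholds
#'
#' Bundle of the numeric decision rules applied throughout the survey:
#' the maximum intervening gap for island chaining, the high-quality
#' prophage gate on CheckV-style completeness/contamination estimates,
#' the PHASTEST-style completeness-score class boundaries, and the
#' (documentation-only) BLAST e-value ceiling for spacer screening.
#'
#' The defaults reproduce the published survey conditions: islands chain
#' features whose intervening distance does not exceed 50,000 bp on the
#' same contig; a prophage passes the quality gate only with *more than*
#' 90% completeness and *less than* 5% contamination (both strict);
#' completeness scores below 70 are incomplete, 70--90 questionable and
#' above 90 intact.
#'
#' `spacer_evalue_max` is retained for the record but never evaluated:
#' because spacer matches must be exact and full-length, an e-value
#' filter at 1e-4 cannot reject any hit on realistic target sizes.
#'
#' @param max_gap_bp Maximum intervening distance (bp) between adjacent
#'   island members; must be positive.
#' @param min_completeness_pct Completeness gate in percent; a record
#'   passes only when strictly above this value.
#' @param max_contamination_pct Contamination gate in percent; a record
#'   passes only when strictly below this value.
#' @param phastest_incomplete_below Scores strictly below this are
#'   classed `incomplete`.
#' @param phastest_intact_above Scores strictly above this are classed
#'   `intact`; scores between the two boundaries (inclusive) are
#'   `questionable`.
#' @param spacer_evalue_max Documentation-only e-value ceiling.
#' @return A list with class `"survey_thresholds"`.
#' @export
#' @examples
#' survey_thresholds()
#' survey_thresholds(max_gap_bp = 25000)
survey_thresholds <- function(max_gap_bp = 50000,
                              min_completeness_pct = 90,
                              max_contamination_pct = 5,
                              phastest_incomplete_below = 70,
                              phastest_intact_above = 90,
                              spacer_evalue_max = 1e-4) {
  if (!is_scalar_number(max_gap_bp) || max_gap_bp <= 0) {
    data_error("max_gap_bp must be a positive number")
  }
  for (p in c(min_completeness_pct, max_contamination_pct)) {
    if (!is_scalar_number(p) || p < 0 || p > 100) {
      data_error("percentage thresholds must lie in [0, 100]")
    }
  }
  if (!is_scalar_number(phastest_incomplete_below) ||
      !is_scalar_number(phastest_intact_above) ||
      phastest_incomplete_below > phastest_intact_above) {
    data_error("score boundaries must be numbers with incomplete_below <= intact_above")
  }
  structure(
    list(
      max_gap_bp = as.numeric(max_gap_bp),
      min_completeness_pct = as.numeric(min_completeness_pct),
      max_contamination_pct = as.numeric(max_contamination_pct),
      phastest_incomplete_below = as.numeric(phastest_incomplete_below),
      phastest_intact_above = as.numeric(phastest_intact_above),
      spacer_evalue_max = as.numeric(spacer_evalue_max)
    ),
    class = "survey_thresholds"
  )
}

#' @export
print.survey_thresholds <- function(x, ...) {
  cat("Survey thresholds\n")
  cat("  island max gap        :", format(x$max_gap_bp, big.mark = ","), "bp\n")
  cat("  quality gate          : completeness >", x$min_completeness_pct,
      "% and contamination <", x$max_contamination_pct, "%\n")
  cat("  score classes         : incomplete <", x$phastest_incomplete_below,
      "<= questionable <=", x$phastest_intact_above, "< intact\n")
  cat("  spacer e-value (doc)  : <=", x$spacer_evalue_max, "\n")
  invisible(x)
}

as_thresholds <- function(x) {
  if (inherits(x, "survey_thresholds")) return(x)
  if (is.list(x)) return(do.call(survey_thresholds, x))
  data_error("thresholds must be built with survey_thresholds()")
}
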