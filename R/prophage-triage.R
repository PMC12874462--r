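# Prophage quality triage: completeness-score classes, the strict
# completeness/contamination quality gate, GC content, and survey
# summary statistics over prophage records.

#' Classify a prophage completeness score
#'
#' PHASTEST-style triage of prophage predictions by completeness score:
#' scores below 70 are `incomplete`, 70 through 90 (inclusive on both
#' boundaries) are `questionable`, and scores above 90 are `intact`.
#' `NA` scores (e.g. predictions from tools that emit no such score)
#' are classed `unscored` rather than rejected.
#'
#' @param score Numeric vector of completeness scores (NA allowed).
#' @param thresholds A [survey_thresholds()] object supplying the
#'   class boundaries.
#' @return Character vector of classes
#'   (`incomplete`/`questionable`/`intact`/`unscored`).
#' @export
#' @examples
#' classify_score(c(69, 70, 90, 91))
classify_score <- function(score, thresholds = survey_thresholds()) {
  thresholds <- as_thresholds(thresholds)
  if (!is.numeric(score)) data_error("score must be numeric")
  if (any(is.infinite(score))) data_error("score must be finite")
  lo <- thresholds$phastest_incomplete_below
  hi <- thresholds$phastest_intact_above
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score < lo] <- "incomplete"
  out[!is.na(score) & score >= lo & score <= hi] <- "questionable"
  out[!is.na(score) & score > hi] <- "intact"
  out[is.na(score)] <- "unscored"
  out
}

#' High-quality prophage gate
#'
#' A prophage passes only with *more than* 90% completeness and *less
#' than* 5% contamination; both inequalities are strict, so records at
#' exactly 90% completeness or exactly 5% contamination fail. The
#' boundaries can be overridden through [survey_thresholds()].
#'
#' @param completeness_pct,contamination_pct Numeric vectors in
#'   `[0, 100]`; out-of-range values are errors, `NA` yields `NA`.
#' @param thresholds A [survey_thresholds()] object.
#' @return Logical vector.
#' @export
#' @examples
#' passes_quality(c(95, 90, 99), c(4.9, 0, 5))  # TRUE FALSE FALSE
passes_quality <- function(completeness_pct, contamination_pct,
                           thresholds = survey_thresholds()) {
  thresholds <- as_thresholds(thresholds)
  for (v in list(completeness_pct, contamination_pct)) {
    if (!is.numeric(v)) data_error("quality percentages must be numeric")
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      data_error("quality percentages must lie in [0, 100]")
    }
  }
  completeness_pct > thresholds$min_completeness_pct &
    contamination_pct < thresholds$max_contamination_pct
}

#' GC content of a nucleotide sequence
#'
#' `100 * (#G + #C) / length`, case-insensitive. IUPAC ambiguity codes
#' (including S) count in the denominator only, a conservative
#' convention for draft prophage sequences.
#'
#' @param sequence Character vector of non-empty IUPAC nucleotide
#'   strings (or a `Biostrings::DNAStringSet`).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' gc_percent(c("GGCC", "aatt", "ACGTN"))  # 100 0 40
gc_percent <- function(sequence) {
  if (inherits(sequence, "XStringSet")) sequence <- as.character(sequence)
  if (!is.character(sequence)) data_error("sequence must be character")
  vapply(sequence, function(s) {
    if (is.na(s) || nchar(s) == 0) data_error("empty sequence")
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), IUPAC_DNA)
    if (length(bad)) {
      data_error("non-IUPAC character '", bad[1], "' in sequence")
    }
    100 * sum(chars %in% c("G", "C")) / length(chars)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a prophage quality table
#'
#' TSV with header `prophage_id`, `genome_id`, `contig_id`, `start`,
#' `end`, `score`, `completeness_pct`, `contamination_pct`; missing
#' numeric cells are empty strings. Optional extra columns `gc_pct` and
#' `length_kbp` are kept when present.
#'
#' @param path File path or connection.
#' @return Tibble of prophage records.
#' @export
read_prophage_quality <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("prophage_id", "genome_id", "contig_id", "start", "end",
                "score", "completeness_pct", "contamination_pct")
  miss <- setdiff(required, names(tbl))
  if (length(miss)) {
    data_error("quality table missing columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("start", "end", "score", "completeness_pct",
                "contamination_pct", "gc_pct", "length_kbp")) {
    if (!is.null(tbl[[col]])) tbl[[col]] <- as.numeric(tbl[[col]])
  }
  tibble::as_tibble(tbl)
}

#' Triage prophage records
#'
#' Applies [classify_score()] and [passes_quality()] to a table of
#' prophage records and derives `length_kbp` from coordinates when
#' absent (`(end - start + 1) / 1000`).
#'
#' @param records Tibble of prophage records (see
#'   [read_prophage_quality()]).
#' @param thresholds A [survey_thresholds()] object.
#' @return The records with `length_kbp`, `triage_class` and
#'   `high_quality` columns filled in.
#' @export
triage_prophages <- function(records, thresholds = survey_thresholds()) {
  thresholds <- as_thresholds(thresholds)
  records <- tibble::as_tibble(records)
  if (is.null(records[["length_kbp"]])) records$length_kbp <- NA_real_
  have_coords <- !is.na(records$start) & !is.na(records$end)
  derived <- (records$end - records$start + 1) / 1000
  fill <- is.na(records$length_kbp) & have_coords
  records$length_kbp[fill] <- derived[fill]
  inconsistent <- which(!is.na(records$length_kbp) & have_coords &
                          abs(records$length_kbp - derived) > 0.05)
  if (length(inconsistent)) {
    data_error("length_kbp inconsistent with coordinates for '",
               records$prophage_id[inconsistent[1]], "'")
  }
  records$triage_class <- classify_score(records$score, thresholds)
  records$high_quality <- passes_quality(records$completeness_pct,
                                         records$contamination_pct,
                                         thresholds)
  records
}

#' Summarize prophage characteristics
#'
#' Arithmetic mean and extrema of genome length (kbp) and GC content
#' over a set of prophage records, the headline statistics of a
#' prophage survey.
#'
#' @param records Tibble with `length_kbp` and `gc_pct` columns; at
#'   least one record required.
#' @return One-row tibble: `n`, `mean_length_kbp`, `min_length_kbp`,
#'   `max_length_kbp`, `mean_gc_pct`, `min_gc_pct`, `max_gc_pct`.
#' @export
#' @examples
#' summarize_prophages(example_prophages())
summarize_prophages <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) data_error("cannot summarize zero prophage records")
  if (is.null(records[["length_kbp"]]) || is.null(records[["gc_pct"]])) {
    data_error("records need length_kbp and gc_pct columns")
  }
  tibble::tibble(
    n = nrow(records),
    mean_length_kbp = mean(records$length_kbp),
    min_length_kbp = min(records$length_kbp),
    max_length_kbp = max(records$length_kbp),
    mean_gc_pct = mean(records$gc_pct),
    min_gc_pct = min(records$gc_pct),
    max_gc_pct = max(records$gc_pct)
  )
}

#' Tally prophage triage classes
#'
#' Counts records per completeness class. Unscored records are reported
#' separately and excluded from the class counts and total, so the total
#' matches the number of score-classified predictions.
#'
#' @param records Tibble with a `triage_class` column, or a character
#'   vector of classes.
#' @return List with `counts` (named integer vector over
#'   intact/questionable/incomplete), `total`, and `n_unscored`.
#' @export
#' @examples
#' tally_triage(rep(c("intact", "questionable", "incomplete"), c(15, 10, 12)))
tally_triage <- function(records) {
  classes <- if (is.data.frame(records)) records$triage_class else records
  classes <- as.character(classes)
  bad <- setdiff(stats::na.omit(unique(classes)), TRIAGE_CLASSES)
  if (length(bad)) data_error("unknown triage class '", bad[1], "'")
  scored <- c("intact", "questionable", "incomplete")
  counts <- vapply(scored, function(cl) sum(classes == cl, na.rm = TRUE),
                   integer(1))
  list(counts = counts, total = sum(counts),
       n_unscored = sum(classes == "unscored", na.rm = TRUE))
}

#' Collapse overlapping prophage calls
#'
#' Optional deduplication utility for predictions of the same region by
#' different tools: records on the same genome and contig whose
#' reciprocal coordinate overlap is at least `min_reciprocal_overlap`
#' are collapsed to the record with the highest completeness (ties:
#' highest score, then first id). The overlap fraction is a pragmatic
#' default, not a published value; choose it to suit the upstream
#' callers.
#'
#' @param records Tibble of prophage records with coordinates.
#' @param min_reciprocal_overlap Fraction in (0, 1]; default 0.5.
#' @return Deduplicated tibble.
#' @export
collapse_overlapping_prophages <- function(records,
                                           min_reciprocal_overlap = 0.5) {
  records <- tibble::as_tibble(records)
  if (nrow(records) < 2) return(records)
  if (is.null(records[["score"]])) records$score <- NA_real_
  if (is.null(records[["completeness_pct"]])) records$completeness_pct <- NA_real_
  keep <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(records) - 1)) {
    if (!keep[i]) next
    for (j in seq(i + 1, nrow(records))) {
      if (!keep[j]) next
      if (records$genome_id[i] != records$genome_id[j] ||
          records$contig_id[i] != records$contig_id[j]) next
      ov <- min(records$end[i], records$end[j]) -
        max(records$start[i], records$start[j]) + 1
      if (is.na(ov) || ov <= 0) next
      len_i <- records$end[i] - records$start[i] + 1
      len_j <- records$end[j] - records$start[j] + 1
      if (ov / len_i < min_reciprocal_overlap ||
          ov / len_j < min_reciprocal_overlap) next
      ci <- records$completeness_pct[i]
      cj <- records$completeness_pct[j]
      drop_j <- isTRUE(cj < ci) || (!isTRUE(cj > ci) &&
        !isTRUE(records$score[j] > records$score[i]))
      if (drop_j) keep[j] <- FALSE else keep[i] <- FALSE
      if (!keep[i]) break
    }
  }
  records[keep, ]
}
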