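# Spatial-proximity island detection: chain same-contig features whose
# intervening gaps stay within a threshold (50 kb by default), require a
# biosynthetic (metabolic) anchor, classify the island architecture, and
# record coordinate overlaps between members.

ISLAND_CLASS_LABELS <- c(
  "defense-metabolite",
  "CRISPR-metabolite",
  "Cas-metabolite",
  "CRISPR-defense-metabolite",
  "Cas-defense-metabolite",
  "combined CRISPR-Cas-defense-metabolite",
  "prophage-metabolite",
  "prophage-defensive-metabolic"
)

#' Island class vocabulary
#'
#' The closed set of island labels emitted by [classify_island()].
#' @return Character vector of labels.
#' @export
island_classes <- function() ISLAND_CLASS_LABELS

#' Intervening gap between two features
#'
#' Number of bases strictly between two spans on the same contig:
#' `max(0, b$start - a$end - 1)`. Overlapping or abutting features have
#' gap 0. This is the distance the island chaining rule compares against
#' the 50 kb threshold.
#'
#' @param a,b Single features (one-row data frames or lists with
#'   `contig_id`, `start`, `end`), `a` preceding `b` in sort order.
#' @return Integer gap in bp.
#' @export
#' @examples
#' a <- list(contig_id = "c", start = 746012, end = 777519)
#' b <- list(contig_id = "c", start = 804690, end = 805508)
#' gap_bp(a, b)  # 27170
gap_bp <- function(a, b) {
  if (!identical(as.character(a$contig_id), as.character(b$contig_id))) {
    data_error("gap_bp requires features on the same contig (",
               a$contig_id, " vs ", b$contig_id, ")")
  }
  as.integer(max(0, b$start - a$end - 1))
}

#' Chain features on one contig by maximum intervening gap
#'
#' Single-linkage chaining of position-sorted features: a feature joins
#' the open cluster when the intervening distance between it and the
#' rightmost base covered so far is at most `max_gap_bp`; otherwise a new
#' cluster starts. Using the running maximum end (rather than only the
#' immediately preceding feature's end) makes the partition equal to the
#' transitive closure of the pairwise gap relation even when features are
#' nested; for non-nested features the two are identical.
#'
#' @param features Tibble of features on one contig, sorted by
#'   `(start, end, feature_id)`; unsorted input is an error.
#' @param max_gap_bp Positive gap threshold in bp.
#' @return List of tibbles, one per cluster, in positional order. Every
#'   input feature lands in exactly one cluster.
#' @export
chain_contig <- function(features, max_gap_bp) {
  if (!is_scalar_number(max_gap_bp) || max_gap_bp <= 0) {
    data_error("max_gap_bp must be a positive number")
  }
  n <- nrow(features)
  if (n == 0) return(list())
  if (length(unique(features$contig_id)) > 1) {
    data_error("chain_contig expects features from a single contig")
  }
  ord <- order(features$start, features$end, features$feature_id)
  if (!identical(ord, seq_len(n))) {
    data_error("features must be sorted by (start, end, feature_id); ",
               "use detect_islands() for unsorted input")
  }
  if (n == 1) return(list(features))
  run_end <- cummax(features$end)
  gaps <- pmax(0, features$start[-1] - run_end[-n] - 1)
  cluster <- cumsum(c(1L, as.integer(gaps > max_gap_bp)))
  unname(split(features, cluster))
}

#' Classify an island by its member categories
#'
#' Pure function of the set of member categories. Every island must
#' contain at least one BGC (the metabolic anchor) and at least one
#' non-BGC element; clusters failing that are not islands and yield
#' `NA`. Any cluster combining a prophage with defensive elements
#' (CRISPR array, Cas cluster or other defense system) is
#' `"prophage-defensive-metabolic"`; a prophage alone with BGCs is
#' `"prophage-metabolite"`. Purely defensive combinations subtype the
#' defensive component: `"defense-metabolite"`, `"CRISPR-metabolite"`,
#' `"Cas-metabolite"`, `"combined CRISPR-Cas-defense-metabolite"` (when
#' both a CRISPR array and a Cas cluster are present, with or without
#' further defense systems), and the compound labels
#' `"CRISPR-defense-metabolite"` / `"Cas-defense-metabolite"` for the
#' remaining two-way combinations.
#'
#' @param members Tibble of cluster members (needs a `category` column),
#'   or a character vector of categories.
#' @return A label from [island_classes()], or `NA_character_` when the
#'   cluster is not an island.
#' @export
#' @examples
#' classify_island(c("CRISPR_ARRAY", "CAS_CLUSTER", "DEFENSE_SYSTEM", "BGC"))
#' classify_island(c("BGC", "PROPHAGE"))
#' classify_island(c("BGC", "BGC"))  # NA: no non-metabolic element
classify_island <- function(members) {
  cats <- if (is.data.frame(members)) members$category else members
  if (length(cats) == 0) data_error("cannot classify an empty cluster")
  bad <- setdiff(cats, FEATURE_CATEGORIES)
  if (length(bad)) data_error("unknown category '", bad[1], "'")
  cats <- unique(cats)
  if (!"BGC" %in% cats || length(cats) == 1) return(NA_character_)
  has <- FEATURE_CATEGORIES %in% cats
  names(has) <- FEATURE_CATEGORIES
  if (has[["PROPHAGE"]]) {
    if (has[["CRISPR_ARRAY"]] || has[["CAS_CLUSTER"]] ||
        has[["DEFENSE_SYSTEM"]]) {
      return("prophage-defensive-metabolic")
    }
    return("prophage-metabolite")
  }
  key <- paste(sort(intersect(cats, c("CRISPR_ARRAY", "CAS_CLUSTER",
                                      "DEFENSE_SYSTEM"))), collapse = "+")
  switch(key,
    "DEFENSE_SYSTEM" = "defense-metabolite",
    "CRISPR_ARRAY" = "CRISPR-metabolite",
    "CAS_CLUSTER" = "Cas-metabolite",
    "CAS_CLUSTER+CRISPR_ARRAY" = "combined CRISPR-Cas-defense-metabolite",
    "CAS_CLUSTER+CRISPR_ARRAY+DEFENSE_SYSTEM" =
      "combined CRISPR-Cas-defense-metabolite",
    "CRISPR_ARRAY+DEFENSE_SYSTEM" = "CRISPR-defense-metabolite",
    "CAS_CLUSTER+DEFENSE_SYSTEM" = "Cas-defense-metabolite",
    data_error("unhandled category combination: ", key)
  )
}

#' Record coordinate overlaps between island members
#'
#' One record per unordered pair of members whose spans intersect,
#' capturing embedded and partially overlapping annotations (e.g. a
#' defense system completely inside a BGC). `feature_a` is the earlier
#' member in sort order; `relation` is `"identical"` for equal spans,
#' `"contains"` / `"contained_by"` when one span fully covers the other,
#' else `"partial"`.
#'
#' @param members Sorted tibble of island members.
#' @return Tibble with columns `feature_a`, `feature_b`, `relation`,
#'   `overlap_bp` (zero rows when no spans intersect).
#' @export
detect_overlaps <- function(members) {
  empty <- tibble::tibble(feature_a = character(0), feature_b = character(0),
                          relation = character(0), overlap_bp = integer(0))
  n <- nrow(members)
  if (n < 2) return(empty)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ov <- min(members$end[i], members$end[j]) -
        max(members$start[i], members$start[j]) + 1
      if (ov <= 0) next
      si <- members$start[i]; ei <- members$end[i]
      sj <- members$start[j]; ej <- members$end[j]
      relation <- if (si == sj && ei == ej) {
        "identical"
      } else if (si <= sj && ei >= ej) {
        "contains"
      } else if (sj <= si && ej >= ei) {
        "contained_by"
      } else {
        "partial"
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature_a = members$feature_id[i],
        feature_b = members$feature_id[j],
        relation = relation,
        overlap_bp = as.integer(ov)
      )
    }
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}

#' Detect multi-functional genomic islands
#'
#' Runs the full island pipeline on an annotation set: per contig, sort
#' features, chain them with [chain_contig()] at the gap threshold,
#' classify each cluster with [classify_island()], and populate member
#' gaps and overlap records. Clusters without a valid island class
#' (no BGC, or nothing but BGCs) are dropped from the result; pass
#' `keep_nonislands = TRUE` to get them back as an attribute.
#'
#' @param x An [annotation_set()], or a feature data frame (possibly
#'   multi-genome, in which case genomes are processed independently and
#'   results concatenated).
#' @param thresholds A [survey_thresholds()] object; only `max_gap_bp`
#'   is used here.
#' @param keep_nonislands Also report clusters that failed
#'   classification (attribute `"non_islands"`).
#' @return Tibble with one row per island: `island_id`
#'   (`genome:contig:ordinal`), `genome_id`, `contig_id`, `span_start`,
#'   `span_end`, `island_class`, `n_members`, `max_gap_bp_observed`,
#'   `n_overlaps`, plus list-columns `members` (tibble of member
#'   features), `gaps_bp` (integer vector, length `n_members - 1`) and
#'   `overlaps` (tibble of overlap records).
#' @export
#' @examples
#' ex <- worked_example("tgb10")
#' detect_islands(ex$features)
detect_islands <- function(x, thresholds = survey_thresholds(),
                           keep_nonislands = FALSE) {
  thresholds <- as_thresholds(thresholds)
  if (!inherits(x, "annotation_set") && is.data.frame(x) &&
      length(unique(x$genome_id)) > 1) {
    sets <- lapply(split(tibble::as_tibble(x), x$genome_id), annotation_set)
    parts <- lapply(sets[order(names(sets))], detect_islands,
                    thresholds = thresholds,
                    keep_nonislands = keep_nonislands)
    out <- dplyr::bind_rows(parts)
    if (keep_nonislands) {
      attr(out, "non_islands") <-
        dplyr::bind_rows(lapply(parts, attr, "non_islands"))
    }
    return(out)
  }
  set <- if (inherits(x, "annotation_set")) x else annotation_set(x)
  feats <- set$features
  islands <- list()
  nonislands <- list()
  for (contig in sort(unique(feats$contig_id))) {
    cf <- sort_features(feats[feats$contig_id == contig, ])
    clusters <- chain_contig(cf, thresholds$max_gap_bp)
    ordinal <- 0L
    for (members in clusters) {
      label <- classify_island(members)
      if (is.na(label)) {
        if (keep_nonislands) {
          nonislands[[length(nonislands) + 1]] <- tibble::tibble(
            genome_id = set$genome_id,
            contig_id = contig,
            span_start = min(members$start),
            span_end = max(members$end),
            n_members = nrow(members),
            categories = paste(members$category, collapse = ","),
            members = list(members)
          )
        }
        next
      }
      ordinal <- ordinal + 1L
      gaps <- member_gaps(members)
      overlaps <- detect_overlaps(members)
      islands[[length(islands) + 1]] <- tibble::tibble(
        island_id = sprintf("%s:%s:%d", set$genome_id, contig, ordinal),
        genome_id = set$genome_id,
        contig_id = contig,
        span_start = min(members$start),
        span_end = max(members$end),
        island_class = label,
        n_members = nrow(members),
        max_gap_bp_observed = if (length(gaps)) max(gaps) else 0L,
        n_overlaps = nrow(overlaps),
        members = list(members),
        gaps_bp = list(gaps),
        overlaps = list(overlaps)
      )
    }
  }
  out <- if (length(islands)) dplyr::bind_rows(islands) else empty_island_tbl()
  if (keep_nonislands) {
    attr(out, "non_islands") <- if (length(nonislands)) {
      dplyr::bind_rows(nonislands)
    } else {
      tibble::tibble(genome_id = character(0), contig_id = character(0),
                     span_start = integer(0), span_end = integer(0),
                     n_members = integer(0), categories = character(0),
                     members = list())
    }
  }
  out
}

# Gap between each member and the rightmost base of the preceding
# members (so nested members report gap 0, consistent with chaining).
member_gaps <- function(members) {
  n <- nrow(members)
  if (n < 2) return(integer(0))
  run_end <- cummax(members$end)
  as.integer(pmax(0, members$start[-1] - run_end[-n] - 1))
}

empty_island_tbl <- function() {
  tibble::tibble(
    island_id = character(0), genome_id = character(0),
    contig_id = character(0), span_start = integer(0),
    span_end = integer(0), island_class = character(0),
    n_members = integer(0), max_gap_bp_observed = integer(0),
    n_overlaps = integer(0), members = list(), gaps_bp = list(),
    overlaps = list()
  )
}
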