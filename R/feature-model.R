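# Core data model: validated per-genome sets of annotated genomic features
# (BGCs, defense systems, CRISPR arrays, Cas clusters, prophages), all with
# 1-based inclusive coordinates.

#' Build a tibble of genomic features
#'
#' Vectorized constructor for annotated genomic elements. Coordinates are
#' 1-based and inclusive, matching how bacterial annotation reports print
#' spans. Each row is one element; linked multi-gene components supplied
#' as separate rows are kept as separate elements.
#'
#' @param genome_id,contig_id Character vectors (recycled to length).
#' @param start,end Integer-like positions, `1 <= start <= end`.
#' @param category One of `"BGC"`, `"DEFENSE_SYSTEM"`, `"CRISPR_ARRAY"`,
#'   `"CAS_CLUSTER"`, `"PROPHAGE"`. Anti-defense systems are ingested as
#'   `DEFENSE_SYSTEM` with a `"anti:"` subtype prefix and count as
#'   defensive elements downstream.
#' @param subtype Free-text product/system label (e.g. `"ectoine"`,
#'   `"RM_Type_I"`, `"Hachiman"`). Hybrid BGCs are one feature whose
#'   subtype is a comma-joined sorted list of product classes.
#' @param source Name of the upstream annotator.
#' @param strand `"+"`, `"-"` or `"unknown"`; ignored by clustering.
#' @param feature_id Optional unique ids; when `NULL`, deterministic ids
#'   of the form `genome:contig:start-end:category` are assigned (with a
#'   `#k` suffix for exact duplicates).
#' @return A tibble with one row per feature, sorted by
#'   `(contig_id, start, end, feature_id)`.
#' @export
#' @examples
#' genomic_features("g1", "ctg1", c(100, 5000), c(900, 9000),
#'                  c("BGC", "DEFENSE_SYSTEM"),
#'                  subtype = c("ectoine", "RM_Type_I"))
genomic_features <- function(genome_id, contig_id, start, end, category,
                             subtype = "", source = "manual",
                             strand = "unknown", feature_id = NULL) {
  n <- max(length(genome_id), length(contig_id), length(start),
           length(end), length(category))
  tbl <- tibble::tibble(
    feature_id = if (is.null(feature_id)) NA_character_ else as.character(feature_id),
    genome_id = rep_len(as.character(genome_id), n),
    contig_id = rep_len(as.character(contig_id), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    category = rep_len(as.character(category), n),
    subtype = rep_len(as.character(subtype), n),
    source = rep_len(as.character(source), n),
    strand = rep_len(as.character(strand), n)
  )
  validate_feature_tbl(tbl)
}

# Validates coordinates/categories, assigns missing feature ids
# deterministically, enforces id uniqueness and returns sorted rows.
# `line` optionally maps rows to input line numbers for error messages.
validate_feature_tbl <- function(tbl, line = NULL) {
  where <- function(i) {
    if (is.null(line)) paste0("row ", i) else paste0("line ", line[i])
  }
  if (nrow(tbl) == 0) {
    tbl$start <- as.integer(tbl$start)
    tbl$end <- as.integer(tbl$end)
    return(tbl[, FEATURE_COLUMNS])
  }
  start <- suppressWarnings(as.numeric(tbl$start))
  end <- suppressWarnings(as.numeric(tbl$end))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad)) {
    data_error("non-numeric coordinates at ", where(bad[1]))
  }
  bad <- which(start < 1 | start != floor(start) | end != floor(end))
  if (length(bad)) {
    data_error("coordinates must be positive integers (1-based) at ", where(bad[1]))
  }
  bad <- which(start > end)
  if (length(bad)) {
    data_error("start > end at ", where(bad[1]))
  }
  tbl$start <- as.integer(start)
  tbl$end <- as.integer(end)
  bad <- which(!tbl$category %in% FEATURE_CATEGORIES)
  if (length(bad)) {
    data_error("unknown category '", tbl$category[bad[1]], "' at ", where(bad[1]),
               " (expected one of ", paste(FEATURE_CATEGORIES, collapse = ", "), ")")
  }
  tbl$subtype[is.na(tbl$subtype)] <- ""
  tbl$source[is.na(tbl$source)] <- "unknown"
  tbl$strand[is.na(tbl$strand) | tbl$strand == "."] <- "unknown"
  bad <- which(!tbl$strand %in% STRAND_VALUES)
  if (length(bad)) {
    data_error("invalid strand '", tbl$strand[bad[1]], "' at ", where(bad[1]))
  }
  # Deterministic auto ids: assign in coordinate order so the result does
  # not depend on input row order.
  ord <- order(tbl$genome_id, tbl$contig_id, tbl$start, tbl$end,
               tbl$category, tbl$subtype)
  tbl <- tbl[ord, ]
  if (!is.null(line)) line <- line[ord]
  missing_id <- is.na(tbl$feature_id) | tbl$feature_id == ""
  if (any(missing_id)) {
    base <- sprintf("%s:%s:%d-%d:%s", tbl$genome_id, tbl$contig_id,
                    tbl$start, tbl$end, tbl$category)
    reps <- stats::ave(seq_along(base), base, FUN = seq_along)
    nrep <- stats::ave(seq_along(base), base, FUN = length)
    auto <- ifelse(nrep > 1, paste0(base, "#", reps), base)
    tbl$feature_id[missing_id] <- auto[missing_id]
  }
  dup <- which(duplicated(tbl$feature_id))
  if (length(dup)) {
    data_error("duplicate feature_id '", tbl$feature_id[dup[1]], "'")
  }
  sort_features(tbl[, FEATURE_COLUMNS])
}

FEATURE_COLUMNS <- c("feature_id", "genome_id", "contig_id", "start", "end",
                     "category", "subtype", "source", "strand")

sort_features <- function(tbl) {
  tbl[order(tbl$contig_id, tbl$start, tbl$end, tbl$feature_id), ]
}

#' Create a per-genome annotation set
#'
#' An annotation set groups the validated features of one genome; all
#' downstream island detection operates on these. Features are stored
#' sorted by `(contig_id, start, end, feature_id)`, the total and
#' deterministic order used for chaining adjacency.
#'
#' @param features A data frame of features (see [genomic_features()] for
#'   the columns; missing `subtype`, `source`, `strand`, `feature_id`
#'   get defaults).
#' @param genome_id Genome identifier; inferred from the features when
#'   unambiguous.
#' @return An object of class `"annotation_set"` with elements
#'   `genome_id` and `features` (sorted tibble).
#' @export
#' @examples
#' fx <- genomic_features("g1", "ctg1", 100, 900, "BGC", "ectoine")
#' annotation_set(fx)
annotation_set <- function(features, genome_id = NULL) {
  tbl <- as_feature_input(features)
  tbl <- validate_feature_tbl(tbl)
  gids <- unique(tbl$genome_id)
  if (is.null(genome_id)) {
    if (length(gids) > 1) {
      data_error("features span multiple genome_ids (",
                 paste(gids, collapse = ", "),
                 "); supply genome_id or split the table first")
    }
    genome_id <- if (length(gids) == 1) gids else NA_character_
  } else {
    stopifnot_scalar_string(genome_id, "genome_id")
    if (nrow(tbl) > 0 && !all(tbl$genome_id == genome_id)) {
      data_error("features carry genome_ids other than '", genome_id, "'")
    }
  }
  structure(list(genome_id = genome_id, features = tbl),
            class = "annotation_set")
}

as_feature_input <- function(features) {
  if (inherits(features, "annotation_set")) return(features$features)
  if (!is.data.frame(features)) {
    data_error("features must be a data frame or annotation_set")
  }
  tbl <- tibble::as_tibble(features)
  required <- c("genome_id", "contig_id", "start", "end", "category")
  miss <- setdiff(required, names(tbl))
  if (length(miss)) {
    data_error("missing feature columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(tbl[["feature_id"]])) tbl$feature_id <- NA_character_
  if (is.null(tbl[["subtype"]])) tbl$subtype <- ""
  if (is.null(tbl[["source"]])) tbl$source <- "unknown"
  if (is.null(tbl[["strand"]])) tbl$strand <- "unknown"
  tbl[, FEATURE_COLUMNS]
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> genome:", x$genome_id %||% NA, "\n")
  cat("  ", nrow(x$features), " features on ",
      length(unique(x$features$contig_id)), " contig(s)\n", sep = "")
  if (nrow(x$features)) {
    print(table(x$features$category))
  }
  invisible(x)
}

#' @export
as.data.frame.annotation_set <- function(x, ...) {
  as.data.frame(x$features, ...)
}

#' Merge annotation sets from multiple upstream sources
#'
#' Takes the union of features from several single-genome sets (for
#' example, BGC calls from one annotator and defense-system calls from
#' another) into one validated, sorted set. Feature ids must be unique
#' across sources.
#'
#' @param sets A list of `annotation_set` objects (or data frames), or
#'   several such objects as `...`.
#' @param ... Additional sets.
#' @return A merged `annotation_set`.
#' @export
#' @examples
#' a <- annotation_set(genomic_features("g1", "c1", 1, 10, "BGC"))
#' b <- annotation_set(genomic_features("g1", "c1", 100, 200, "PROPHAGE"))
#' merge_sources(a, b)
merge_sources <- function(sets, ...) {
  if (inherits(sets, "annotation_set") || is.data.frame(sets)) {
    sets <- c(list(sets), list(...))
  }
  if (!length(sets)) data_error("no annotation sets supplied")
  sets <- lapply(sets, function(s) {
    if (inherits(s, "annotation_set")) s else annotation_set(s)
  })
  gids <- unique(unlist(lapply(sets, function(s) {
    if (nrow(s$features)) s$genome_id else character(0)
  })))
  if (length(gids) > 1) {
    data_error("cannot merge sets with mixed genome_ids: ",
               paste(gids, collapse = ", "))
  }
  combined <- dplyr::bind_rows(lapply(sets, function(s) s$features))
  dup <- combined$feature_id[duplicated(combined$feature_id)]
  if (length(dup)) {
    data_error("duplicate feature_id across sources: ", dup[1])
  }
  annotation_set(combined,
                 genome_id = if (length(gids)) gids else
                   sets[[1]]$genome_id)
}
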