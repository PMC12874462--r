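# Survey-level tallies: count tables with full-precision shares,
# hybrid-aware BGC class counts, per-group ribbon exports for circular
# plots, and a rare-codon (TTA) tally.

#' Count table with shares
#'
#' Tallies a key vector into counts and percentage shares
#' (`100 * count / total`, kept at full precision; use [format_pct()]
#' for display). Rows are ordered by count descending, then key
#' ascending, so outputs are deterministic.
#'
#' @param keys Character vector (one entry per record), e.g. Cas gene
#'   types, defense-system names or island classes.
#' @return Tibble with `key`, `count`, `share_pct`; the grand total is
#'   attached as attribute `"total"`. Empty input gives a zero-row
#'   table with total 0.
#' @export
#' @examples
#' ct <- count_table(rep(c("Cas3_TypeI", "other"), c(58, 90)))
#' ct$share_pct[ct$key == "Cas3_TypeI"]  # 39.189...
count_table <- function(keys) {
  keys <- as.character(keys)
  keys <- keys[!is.na(keys)]
  if (length(keys) == 0) {
    out <- tibble::tibble(key = character(0), count = integer(0),
                          share_pct = numeric(0))
    attr(out, "total") <- 0L
    return(out)
  }
  tab <- table(keys)
  out <- tibble::tibble(key = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$key), ]
  total <- sum(out$count)
  out$share_pct <- 100 * out$count / total
  attr(out, "total") <- total
  out
}

#' Tally BGC classes with explicit hybrid handling
#'
#' Hybrid BGCs are single features whose subtype is a comma-joined list
#' of product classes (e.g. `"arylpolyene,resorcinol"`). Because a
#' survey reports both per-class prevalence and hybrids as entities,
#' two tables are returned: `single` counts every component class once
#' per feature carrying it (so one hybrid contributes to each of its
#' classes), and `hybrid` counts multi-class combinations keyed by the
#' sorted `+`-joined label.
#'
#' @param features Feature tibble (only `category == "BGC"` rows are
#'   used) or a character vector of BGC subtypes.
#' @return List of two count tables, `single` and `hybrid`.
#' @export
#' @examples
#' tally_bgc(c("ectoine", "ectoine", "T3PKS,terpene"))
tally_bgc <- function(features) {
  subtypes <- if (is.data.frame(features)) {
    features$subtype[features$category == "BGC"]
  } else {
    as.character(features)
  }
  parts <- strsplit(subtypes, ",", fixed = TRUE)
  parts <- lapply(parts, function(p) sort(trimws(p[nzchar(trimws(p))])))
  single <- count_table(unlist(parts))
  hybrids <- parts[lengths(parts) > 1]
  hybrid <- count_table(vapply(hybrids, paste, character(1), collapse = "+"))
  list(single = single, hybrid = hybrid)
}

#' Per-group ribbon export for circular plots
#'
#' Produces the long table behind ribbon/chord visualizations linking
#' groups (genomes or species) to feature keys (e.g. Cas types): one
#' row per `(group, key)` with the absolute count and that key's share
#' within the group.
#'
#' @param x Either a data frame with `group` and `key` columns (one row
#'   per record), or a named list of per-group count tables / key
#'   vectors. Empty groups are skipped with a warning.
#' @return Tibble with `group`, `key`, `count`, `group_share_pct`,
#'   ordered by group then count descending.
#' @export
#' @examples
#' ribbon_export(data.frame(group = c("g1", "g1", "g2"),
#'                          key = c("x", "y", "x")))
ribbon_export <- function(x) {
  if (is.data.frame(x)) {
    if (is.null(x[["group"]]) || is.null(x[["key"]])) {
      data_error("ribbon input needs group and key columns")
    }
    groups <- split(as.character(x$key), as.character(x$group))
  } else if (is.list(x)) {
    if (is.null(names(x))) data_error("per-group list must be named")
    groups <- lapply(x, function(g) {
      if (is.data.frame(g)) rep(g$key, g$count) else as.character(g)
    })
  } else {
    data_error("unsupported ribbon input")
  }
  rows <- list()
  for (grp in sort(names(groups))) {
    ct <- count_table(groups[[grp]])
    if (nrow(ct) == 0) {
      warning("skipping empty group '", grp, "'", call. = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      group = grp, key = ct$key, count = ct$count,
      group_share_pct = ct$share_pct
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(group = character(0), key = character(0),
                          count = integer(0), group_share_pct = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Count in-frame TTA codons
#'
#' Tallies occurrences of the rare leucine codon TTA read in a fixed
#' frame of the given strand representation of a coding sequence. TTA
#' abundance in defense genes is of interest because translation of
#' TTA-rich genes is gated by the scarce corresponding leucyl-tRNA,
#' a candidate co-regulatory signal for co-located defense and
#' biosynthetic loci.
#'
#' @param cds Nucleotide string (the strand to read).
#' @param frame Reading-frame offset 0, 1 or 2.
#' @return Integer count. Sequences shorter than 3 nt give 0 with a
#'   warning.
#' @export
#' @examples
#' tta_codon_count("TTATTA")      # 2
#' tta_codon_count("ATTA", frame = 1)  # 1
tta_codon_count <- function(cds, frame = 0) {
  stopifnot_scalar_string(cds, "cds")
  if (!frame %in% 0:2) data_error("frame must be 0, 1 or 2")
  s <- toupper(cds)
  n <- nchar(s)
  if (n < 3) {
    warning("sequence shorter than one codon", call. = FALSE)
    return(0L)
  }
  starts <- seq(1 + frame, n - 2, by = 3)
  if (!length(starts)) return(0L)
  sum(substring(s, starts, starts + 2) == "TTA")
}
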