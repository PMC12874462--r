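# Readers/writers harmonizing annotation tables across dialects.
#
# Internal coordinates are always 1-based inclusive. BED (0-based,
# half-open) is converted on ingest and egest; GFF3 is 1-based inclusive
# already. BED and GFF3 go through rtracklayer; the native TSV is parsed
# line-by-line so malformed rows can be reported with their line number.

NATIVE_TSV_REQUIRED <- c("genome_id", "contig_id", "start", "end",
                         "category", "subtype", "source")
NATIVE_TSV_OPTIONAL <- c("strand", "feature_id")
FEATURES_SCHEMA_VERSION <- "1.0"

#' Read an annotation table into an annotation set
#'
#' Ingests one genome's feature table in any of four dialects and returns
#' a validated [annotation_set()].
#'
#' * `native_tsv`: tab-separated with header columns `genome_id`,
#'   `contig_id`, `start`, `end`, `category`, `subtype`, `source` and
#'   optionally `strand`, `feature_id`. Malformed rows are rejected with
#'   their line number.
#' * `bed`: standard BED (0-based half-open), converted to 1-based
#'   inclusive. BED carries no category column, so either supply
#'   `category` (applied to every interval, with the BED name becoming
#'   the subtype) or encode `"CATEGORY"` / `"CATEGORY:subtype"` in the
#'   name field.
#' * `gff3`: categories are taken from the `category` attribute (the
#'   documented key, as written by [write_features()]); rows lacking it
#'   fall back to the uppercased `type` column when that is a valid
#'   category.
#' * `json`: the schema-versioned export of [write_features()].
#'
#' @param path File path, `"-"` for standard input, or a connection
#'   (e.g. `textConnection`).
#' @param dialect One of `"native_tsv"`, `"bed"`, `"gff3"`, `"json"`.
#' @param genome_id Genome identifier; required for BED (which has no
#'   genome column) and used to check the others.
#' @param category Optional single category applied to all BED intervals.
#' @return An [annotation_set()].
#' @export
#' @examples
#' tsv <- paste(
#'   "genome_id\tcontig_id\tstart\tend\tcategory\tsubtype\tsource",
#'   "TGB10\tctg1\t657024\t657967\tCRISPR_ARRAY\tCRISPR\tCRISPRCasFinder",
#'   sep = "\n")
#' read_feature_table(textConnection(tsv))
read_feature_table <- function(path,
                               dialect = c("native_tsv", "bed", "gff3", "json"),
                               genome_id = NULL, category = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
    native_tsv = read_features_native(path, genome_id),
    bed = read_features_bed(path, genome_id, category),
    gff3 = read_features_gff3(path, genome_id),
    json = read_features_json(path, genome_id)
  )
}

#' Read a multi-genome feature table
#'
#' Convenience wrapper splitting a native TSV carrying several genomes
#' into one [annotation_set()] per genome.
#'
#' @inheritParams read_feature_table
#' @return Named list of annotation sets, keyed by genome id.
#' @export
read_feature_tables <- function(path) {
  tbl <- parse_native_tsv(path)
  if (nrow(tbl) == 0) return(list())
  sets <- lapply(split(tbl, tbl$genome_id), annotation_set)
  sets[order(names(sets))]
}

read_features_native <- function(path, genome_id = NULL) {
  tbl <- parse_native_tsv(path)
  if (nrow(tbl) > 1 && length(unique(tbl$genome_id)) > 1) {
    data_error("table carries multiple genomes; use read_feature_tables()")
  }
  annotation_set(tbl, genome_id = genome_id)
}

# Hand-parsed so errors can name the offending 1-based line number,
# which data-frame readers cannot report.
parse_native_tsv <- function(path) {
  lines <- read_input_lines(path)
  empty <- empty_feature_tbl()
  if (length(lines) == 0 || all(!nzchar(lines))) return(empty)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(NATIVE_TSV_REQUIRED, header)
  if (length(miss)) {
    data_error("line 1: missing required columns: ",
               paste(miss, collapse = ", "))
  }
  unknown <- setdiff(header, c(NATIVE_TSV_REQUIRED, NATIVE_TSV_OPTIONAL))
  if (length(unknown)) {
    data_error("line 1: unknown columns: ", paste(unknown, collapse = ", "))
  }
  body_idx <- which(nzchar(lines))[-1]
  if (!length(body_idx)) return(empty)
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  # trailing empty cells are dropped by strsplit; pad them back
  fields[nf < length(header)] <- lapply(fields[nf < length(header)],
                                        function(f) c(f, rep("", length(header) - length(f))))
  bad <- which(lengths(fields) != length(header))
  if (length(bad)) {
    data_error("line ", body_idx[bad[1]], ": expected ", length(header),
               " tab-separated fields, found ", lengths(fields)[bad[1]])
  }
  mat <- do.call(rbind, fields)
  colnames(mat) <- header
  tbl <- tibble::as_tibble(mat)
  for (col in NATIVE_TSV_OPTIONAL) {
    if (is.null(tbl[[col]])) tbl[[col]] <- NA_character_
  }
  tbl <- tbl[, c(NATIVE_TSV_OPTIONAL[2], NATIVE_TSV_REQUIRED[1:5],
                 "subtype", "source", "strand")]
  names(tbl)[1] <- "feature_id"
  validate_feature_tbl(tbl, line = body_idx)
}

empty_feature_tbl <- function() {
  tibble::tibble(
    feature_id = character(0), genome_id = character(0),
    contig_id = character(0), start = integer(0), end = integer(0),
    category = character(0), subtype = character(0),
    source = character(0), strand = character(0)
  )
}

read_input_lines <- function(path) {
  if (identical(path, "-")) return(readLines(file("stdin")))
  readLines(path)
}

read_features_bed <- function(path, genome_id, category = NULL) {
  if (is.null(genome_id)) {
    data_error("BED input carries no genome column; supply genome_id")
  }
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) {
    return(annotation_set(empty_feature_tbl(), genome_id = genome_id))
  }
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  if (!is.null(category)) {
    cat_vec <- rep(category, length(gr))
    subtype <- ifelse(is.na(nm), "", nm)
  } else {
    if (anyNA(nm)) {
      data_error("BED name field required to carry CATEGORY[:subtype] ",
                 "when no category argument is given")
    }
    cat_vec <- sub(":.*$", "", nm)
    subtype <- ifelse(grepl(":", nm, fixed = TRUE),
                      sub("^[^:]*:", "", nm), "")
  }
  strand_chr <- as.character(BiocGenerics::strand(gr))
  tbl <- tibble::tibble(
    feature_id = NA_character_,
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),  # rtracklayer already shifted to 1-based
    end = BiocGenerics::end(gr),
    category = cat_vec,
    subtype = subtype,
    source = "bed",
    strand = ifelse(strand_chr == "*", "unknown", strand_chr)
  )
  annotation_set(tbl, genome_id = genome_id)
}

read_features_gff3 <- function(path, genome_id = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(annotation_set(empty_feature_tbl(), genome_id = genome_id))
  }
  mc <- S4Vectors::mcols(gr)
  cat_vec <- as.character(mc$category %||% rep(NA_character_, length(gr)))
  type_up <- toupper(as.character(mc$type))
  cat_vec <- ifelse(is.na(cat_vec) & type_up %in% FEATURE_CATEGORIES,
                    type_up, cat_vec)
  if (anyNA(cat_vec)) {
    data_error("GFF3 record without a 'category' attribute or ",
               "category-valued type column")
  }
  gid <- as.character(mc$genome_id %||% rep(NA_character_, length(gr)))
  if (anyNA(gid)) {
    if (is.null(genome_id)) {
      data_error("GFF3 records lack genome_id attributes; supply genome_id")
    }
    gid[is.na(gid)] <- genome_id
  }
  strand_chr <- as.character(BiocGenerics::strand(gr))
  tbl <- tibble::tibble(
    feature_id = as.character(mc$ID %||% rep(NA_character_, length(gr))),
    genome_id = gid,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    category = cat_vec,
    subtype = as.character(mc$subtype %||% rep("", length(gr))),
    source = as.character(mc$source),
    strand = ifelse(strand_chr == "*", "unknown", strand_chr)
  )
  annotation_set(tbl, genome_id = genome_id)
}

read_features_json <- function(path, genome_id = NULL) {
  obj <- jsonlite::fromJSON(if (identical(path, "-")) file("stdin") else path)
  feats <- obj$features
  if (is.null(feats) || length(feats) == 0 ||
      (is.data.frame(feats) && nrow(feats) == 0)) {
    return(annotation_set(empty_feature_tbl(),
                          genome_id = genome_id %||% obj$genome_id))
  }
  annotation_set(tibble::as_tibble(feats),
                 genome_id = genome_id %||% obj$genome_id)
}

#' Write an annotation set
#'
#' Serializes a feature set. `native_tsv` and `json` round-trip
#' losslessly through [read_feature_table()]; `bed` preserves
#' coordinates (converted to 0-based half-open) plus category/subtype in
#' the name field; `gff3` carries `category` and `subtype` as
#' attributes.
#'
#' @param set An [annotation_set()] (or data frame of features).
#' @param path Output path, or `"-"` for standard output.
#' @param format One of `"native_tsv"`, `"gff3"`, `"json"`, `"bed"`.
#' @return The path, invisibly.
#' @export
write_features <- function(set, path,
                           format = c("native_tsv", "gff3", "json", "bed")) {
  format <- match.arg(format)
  if (!inherits(set, "annotation_set")) set <- annotation_set(set)
  switch(format,
    native_tsv = write_features_native(set, path),
    gff3 = write_features_gff3(set, path),
    json = write_features_json(set, path),
    bed = write_features_bed(set, path)
  )
}

write_features_native <- function(set, path) {
  tbl <- set$features[, c("genome_id", "contig_id", "start", "end",
                          "category", "subtype", "source", "strand",
                          "feature_id")]
  atomic_write(path, function(p) {
    utils::write.table(tbl, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
}

write_features_json <- function(set, path) {
  obj <- list(
    schema_version = FEATURES_SCHEMA_VERSION,
    genome_id = set$genome_id,
    features = set$features
  )
  atomic_write(path, function(p) {
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  })
}

features_to_granges <- function(tbl) {
  strand <- ifelse(tbl$strand == "unknown", "*", tbl$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = tbl$contig_id,
    ranges = IRanges::IRanges(start = tbl$start, end = tbl$end),
    strand = strand
  )
  S4Vectors::mcols(gr)$source <- tbl$source
  S4Vectors::mcols(gr)$type <- tolower(tbl$category)
  S4Vectors::mcols(gr)$ID <- tbl$feature_id
  S4Vectors::mcols(gr)$category <- tbl$category
  S4Vectors::mcols(gr)$subtype <- tbl$subtype
  S4Vectors::mcols(gr)$genome_id <- tbl$genome_id
  gr
}

write_features_gff3 <- function(set, path) {
  atomic_write(path, function(p) {
    if (nrow(set$features) == 0) {
      writeLines("##gff-version 3", p)
    } else {
      rtracklayer::export(features_to_granges(set$features), p,
                          format = "gff3")
    }
  })
}

write_features_bed <- function(set, path) {
  tbl <- set$features
  atomic_write(path, function(p) {
    if (nrow(tbl) == 0) {
      writeLines(character(0), p)
      return()
    }
    name <- ifelse(tbl$subtype == "", tbl$category,
                   paste0(tbl$category, ":", tbl$subtype))
    bed <- data.frame(
      chrom = tbl$contig_id,
      chromStart = tbl$start - 1L,  # to 0-based half-open
      chromEnd = tbl$end,
      name = name,
      score = 0L,
      strand = ifelse(tbl$strand == "unknown", ".", tbl$strand)
    )
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  })
}
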