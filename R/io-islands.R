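# Island report writers: flat TSV, GFF3 (island parent + member
# children), and a schema-versioned JSON mirror of the island records.

ISLANDS_SCHEMA_VERSION <- "1.0"

#' Write detected islands
#'
#' @param islands Island tibble from [detect_islands()].
#' @param path Output path, or `"-"` for standard output.
#' @param format `"tsv"` (one flat row per island with comma-joined
#'   member ids), `"gff3"` (a `genomic_island` feature per island with
#'   member child features), or `"json"` (full nested records).
#' @return The path, invisibly.
#' @export
write_islands <- function(islands, path, format = c("tsv", "gff3", "json")) {
  format <- match.arg(format)
  switch(format,
    tsv = write_islands_tsv(islands, path),
    gff3 = write_islands_gff3(islands, path),
    json = write_islands_json(islands, path)
  )
}

#' Flatten an island tibble for tabular output
#'
#' @param islands Island tibble from [detect_islands()].
#' @return Tibble without list-columns; member ids comma-joined.
#' @export
flatten_islands <- function(islands) {
  tibble::tibble(
    island_id = islands$island_id,
    genome_id = islands$genome_id,
    contig_id = islands$contig_id,
    span_start = islands$span_start,
    span_end = islands$span_end,
    island_class = islands$island_class,
    n_members = islands$n_members,
    member_ids = vapply(islands$members,
                        function(m) paste(m$feature_id, collapse = ","),
                        character(1)),
    max_gap_bp_observed = islands$max_gap_bp_observed,
    n_overlaps = islands$n_overlaps
  )
}

write_islands_tsv <- function(islands, path) {
  atomic_write(path, function(p) {
    utils::write.table(flatten_islands(islands), p, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
  })
}

write_islands_json <- function(islands, path) {
  records <- lapply(seq_len(nrow(islands)), function(i) {
    list(
      island_id = islands$island_id[i],
      genome_id = islands$genome_id[i],
      contig_id = islands$contig_id[i],
      span_start = islands$span_start[i],
      span_end = islands$span_end[i],
      island_class = islands$island_class[i],
      n_members = islands$n_members[i],
      members = islands$members[[i]],
      gaps_bp = islands$gaps_bp[[i]],
      overlaps = islands$overlaps[[i]]
    )
  })
  atomic_write(path, function(p) {
    jsonlite::write_json(
      list(schema_version = ISLANDS_SCHEMA_VERSION, islands = records),
      p, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
    )
  })
}

write_islands_gff3 <- function(islands, path) {
  atomic_write(path, function(p) {
    if (nrow(islands) == 0) {
      writeLines("##gff-version 3", p)
      return()
    }
    kids <- dplyr::bind_rows(lapply(seq_len(nrow(islands)), function(i) {
      m <- islands$members[[i]]
      m$parent <- islands$island_id[i]
      m
    }))
    rows <- tibble::tibble(
      contig_id = c(islands$contig_id, kids$contig_id),
      start = c(islands$span_start, kids$start),
      end = c(islands$span_end, kids$end),
      strand = c(rep("*", nrow(islands)),
                 ifelse(kids$strand == "unknown", "*", kids$strand)),
      source = c(rep("islescan", nrow(islands)), kids$source),
      type = c(rep("genomic_island", nrow(islands)), tolower(kids$category)),
      ID = c(islands$island_id, kids$feature_id),
      island_class = c(islands$island_class, rep(NA_character_, nrow(kids))),
      category = c(rep(NA_character_, nrow(islands)), kids$category),
      subtype = c(rep(NA_character_, nrow(islands)), kids$subtype),
      genome_id = c(islands$genome_id, kids$genome_id),
      Parent = c(rep(NA_character_, nrow(islands)), kids$parent)
    )
    gr <- GenomicRanges::GRanges(
      seqnames = rows$contig_id,
      ranges = IRanges::IRanges(start = rows$start, end = rows$end),
      strand = rows$strand
    )
    for (col in c("source", "type", "ID", "island_class", "category",
                  "subtype", "genome_id", "Parent")) {
      S4Vectors::mcols(gr)[[col]] <- rows[[col]]
    }
    rtracklayer::export(gr, p, format = "gff3")
  })
}
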