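# Exact spacer-to-protospacer screening: full-length, zero-mismatch
# matches of CRISPR spacers in prophage sequences, on both strands.
# Because every hit must be exact and span the whole spacer, the usual
# BLAST e-value cutoff can never reject a reported hit and is therefore
# documented in survey_thresholds() but not computed.

SPACER_ALPHABET <- c("A", "C", "G", "T", "N")

COMPLEMENT_FROM <- "ACGTURYSWKMBDHVN"
COMPLEMENT_TO <- "TGCAAYRSWMKVHDBN"

#' Reverse complement
#'
#' Standard reverse complement over the IUPAC alphabet (N maps to N;
#' U is complemented to A). Input is uppercased.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Character vector.
#' @export
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
reverse_complement <- function(seq) {
  if (inherits(seq, "XStringSet")) seq <- as.character(seq)
  if (!is.character(seq)) data_error("sequence must be character")
  up <- toupper(seq)
  bad_idx <- grep(paste0("[^", COMPLEMENT_FROM, "]"), up)
  if (length(bad_idx)) {
    data_error("invalid nucleotide character in sequence ", bad_idx[1])
  }
  comp <- chartr(COMPLEMENT_FROM, COMPLEMENT_TO, up)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_spacer_alphabet <- function(seq, what) {
  bad <- setdiff(unique(strsplit(toupper(seq), "", fixed = TRUE)[[1]]),
                 SPACER_ALPHABET)
  if (length(bad)) {
    data_error(what, " contains invalid character '", bad[1],
               "' (allowed: A/C/G/T/N)")
  }
}

#' Find exact full-length spacer matches in one target
#'
#' Reports every position where the spacer, or its reverse complement,
#' occurs exactly (case-insensitive, zero mismatches, full spacer
#' length) in the target. Overlapping occurrences are all reported. A
#' position involving `N` on either side never matches (conservative:
#' an ambiguous base is not evidence of identity). Positions are 1-based
#' starts on the target's forward strand; hits are sorted by
#' `(position, strand)`.
#'
#' @param spacer_seq Spacer nucleotide string (A/C/G/T/N).
#' @param target_id Identifier of the target sequence.
#' @param target_seq Target nucleotide string.
#' @param spacer_id Identifier recorded in the hits (default
#'   `"spacer"`).
#' @return Tibble with columns `spacer_id`, `target_id`, `position`,
#'   `strand`, `match_len`.
#' @export
#' @examples
#' find_hits("ACGT", "t1", "TTACGTTT")   # one + hit at position 3
#' find_hits("AAAC", "t1", "TGTTTA")     # one - hit at position 2
find_hits <- function(spacer_seq, target_id, target_seq,
                      spacer_id = "spacer") {
  stopifnot_scalar_string(spacer_seq, "spacer_seq")
  stopifnot_scalar_string(target_seq, "target_seq")
  check_spacer_alphabet(spacer_seq, "spacer")
  check_spacer_alphabet(target_seq, "target")
  sp <- toupper(spacer_seq)
  tg <- toupper(target_seq)
  m <- nchar(sp)
  n <- nchar(tg)
  if (m == 0) data_error("spacer sequence is empty")
  if (m < 20 || m > 50) {
    warning("spacer '", spacer_id, "' length ", m,
            " nt is outside the typical 20-50 nt range", call. = FALSE)
  }
  empty <- tibble::tibble(spacer_id = character(0), target_id = character(0),
                          position = integer(0), strand = character(0),
                          match_len = integer(0))
  # N never matches on either side: a spacer containing N can have no
  # exact hit, and an N-free spacer cannot equal a window containing N.
  if (grepl("N", sp, fixed = TRUE) || m > n) return(empty)
  starts <- seq_len(n - m + 1L)
  windows <- substring(tg, starts, starts + m - 1L)
  fwd <- starts[windows == sp]
  rc <- reverse_complement(sp)
  # for a palindromic spacer the reverse-complement occurrence is the
  # same physical match; report it once, on the forward strand
  rev_pos <- if (rc == sp) integer(0) else starts[windows == rc]
  hits <- tibble::tibble(
    spacer_id = spacer_id,
    target_id = target_id,
    position = as.integer(c(fwd, rev_pos)),
    strand = c(rep("+", length(fwd)), rep("-", length(rev_pos))),
    match_len = m
  )
  hits[order(hits$position, hits$strand), ]
}

#' Screen spacers against prophage sequences
#'
#' Runs [find_hits()] over the cross product of spacers and targets and
#' returns the union, in deterministic
#' `(spacer_id, target_id, position, strand)` order.
#'
#' @param spacers Named character vector, `Biostrings::DNAStringSet`, or
#'   tibble with `spacer_id` and `sequence` columns.
#' @param targets Named character vector or `Biostrings::DNAStringSet`
#'   of target (prophage) sequences; duplicated target ids are an
#'   error.
#' @return Tibble of hits (see [find_hits()]).
#' @export
screen_spacers <- function(spacers, targets) {
  spacers <- as_named_seqs(spacers, id_col = "spacer_id")
  targets <- as_named_seqs(targets, id_col = "target_id")
  if (anyDuplicated(names(targets))) {
    data_error("duplicate target ids: ",
               names(targets)[duplicated(names(targets))][1])
  }
  if (anyDuplicated(names(spacers))) {
    data_error("duplicate spacer ids: ",
               names(spacers)[duplicated(names(spacers))][1])
  }
  out <- list()
  for (sid in names(spacers)) {
    for (tid in names(targets)) {
      out[[length(out) + 1]] <-
        find_hits(spacers[[sid]], tid, targets[[tid]], spacer_id = sid)
    }
  }
  hits <- dplyr::bind_rows(out)
  if (nrow(hits) == 0) {
    return(tibble::tibble(spacer_id = character(0), target_id = character(0),
                          position = integer(0), strand = character(0),
                          match_len = integer(0)))
  }
  hits[order(hits$spacer_id, hits$target_id, hits$position, hits$strand), ]
}

as_named_seqs <- function(x, id_col) {
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) data_error("sequences must be named")
    # FASTA headers may carry descriptions after the id
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.data.frame(x)) {
    if (is.null(x[[id_col]]) || is.null(x[["sequence"]])) {
      data_error("sequence table needs ", id_col, " and sequence columns")
    }
    return(stats::setNames(as.character(x$sequence), x[[id_col]]))
  }
  if (is.character(x)) {
    if (is.null(names(x))) data_error("sequences must be named")
    return(x)
  }
  data_error("unsupported sequence container")
}

#' Read spacers from FASTA or TSV
#'
#' FASTA ids become spacer ids; a TSV needs `spacer_id` and `sequence`
#' columns (optional `array_id`, `genome_id` kept when present).
#'
#' @param path File path.
#' @param format `"fasta"` or `"tsv"`.
#' @return Tibble with `spacer_id` and `sequence` (plus any sidecar
#'   columns).
#' @export
read_spacers <- function(path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    return(tibble::tibble(
      spacer_id = sub("\\s.*$", "", names(seqs)),
      sequence = unname(as.character(seqs))
    ))
  }
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (is.null(tbl[["spacer_id"]]) || is.null(tbl[["sequence"]])) {
    data_error("spacer TSV needs spacer_id and sequence columns")
  }
  tibble::as_tibble(tbl)
}

#' Write spacer hits as TSV
#'
#' @param hits Hit tibble from [screen_spacers()].
#' @param path Output path, or `"-"` for standard output.
#' @return The path, invisibly.
#' @export
write_hits <- function(hits, path) {
  atomic_write(path, function(p) {
    utils::write.table(hits, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
}
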