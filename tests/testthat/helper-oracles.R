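# Independent oracles and random-instance builders for property tests.
# These deliberately avoid the package's own chaining/matching code
# paths: clustering is done by brute-force transitive closure over all
# pairs, and spacer matching by a position-by-position sliding window
# with Biostrings supplying the reverse complement.

# Partition as a canonical form: sorted list of sorted feature_id sets.
canonical_partition <- function(groups) {
  ids <- unname(lapply(groups, function(g) sort(unname(g))))
  ids[order(vapply(ids, `[`, character(1), 1))]
}

# Brute force: symmetric gap between every pair of intervals, adjacency
# when gap <= max_gap, then connected components by label propagation.
brute_force_clusters <- function(feats, max_gap) {
  n <- nrow(feats)
  if (n == 0) return(list())
  s <- feats$start
  e <- feats$end
  gap <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gap[i, j] <- max(0, max(s[i], s[j]) - min(e[i], e[j]) - 1)
    }
  }
  adj <- gap <= max_gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      m <- min(comp[adj[i, ]])
      if (m < comp[i]) {
        comp[comp %in% comp[i]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  canonical_partition(split(feats$feature_id, comp))
}

# Random single-contig feature table; the coordinate scale is chosen so
# that moderate thresholds produce a mix of merged and split clusters.
random_contig_tbl <- function(n, genome = "g", contig = "c",
                              span = 400000L, max_len = 30000L) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(
    feature_id = sprintf("f%03d", seq_len(n)),
    genome_id = genome,
    contig_id = contig,
    start = start,
    end = start + len - 1L,
    category = sample(c("BGC", "DEFENSE_SYSTEM", "CRISPR_ARRAY",
                        "CAS_CLUSTER", "PROPHAGE"), n, replace = TRUE),
    subtype = "",
    source = "random",
    strand = "unknown"
  )
}

sort_tbl <- function(tbl) {
  tbl[order(tbl$start, tbl$end, tbl$feature_id), ]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# O(n*m) sliding-window scan; reverse complement via Biostrings so the
# route is independent of the package's chartr-based implementation.
naive_scan <- function(spacer, target, spacer_id = "s", target_id = "t") {
  sp <- toupper(spacer)
  tg <- toupper(target)
  m <- nchar(sp)
  n <- nchar(tg)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sp)))
  rows <- list()
  if (m <= n && !grepl("N", sp, fixed = TRUE)) {
    for (p in seq_len(n - m + 1)) {
      w <- substr(tg, p, p + m - 1)
      if (grepl("N", w, fixed = TRUE)) next
      if (w == sp) {
        rows[[length(rows) + 1]] <- list(position = p, strand = "+")
      }
      # palindromic spacers: the reverse-complement occurrence is the
      # same physical match, reported once on the forward strand
      if (rc != sp && w == rc) {
        rows[[length(rows) + 1]] <- list(position = p, strand = "-")
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(spacer_id = character(0), target_id = character(0),
                          position = integer(0), strand = character(0),
                          match_len = integer(0)))
  }
  out <- tibble::tibble(
    spacer_id = spacer_id,
    target_id = target_id,
    position = vapply(rows, function(r) as.integer(r$position), integer(1)),
    strand = vapply(rows, function(r) r$strand, character(1)),
    match_len = m
  )
  out[order(out$position, out$strand), ]
}

# Small feature-table builder for classification tests.
cat_tbl <- function(categories) {
  n <- length(categories)
  tibble::tibble(
    feature_id = sprintf("x%d", seq_len(n)),
    genome_id = "g", contig_id = "c",
    start = seq(1L, by = 100000L, length.out = n),
    end = seq(1L, by = 100000L, length.out = n) + 999L,
    category = categories, subtype = "", source = "t", strand = "unknown"
  )
}
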