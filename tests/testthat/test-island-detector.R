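# Island chaining, classification, overlap recording and the full
# detector, including property checks against a brute-force oracle.

test_that("gap_bp is the count of bases strictly between spans", {
  a <- list(contig_id = "c", start = 746012L, end = 777519L)
  b <- list(contig_id = "c", start = 804690L, end = 805508L)
  expect_equal(gap_bp(a, b), 27170L)
  a2 <- list(contig_id = "c", start = 3415756L, end = 3438299L)
  b2 <- list(contig_id = "c", start = 3477714L, end = 3537879L)
  expect_equal(gap_bp(a2, b2), 39414L)
  # overlapping / identical / abutting spans all give 0
  expect_equal(gap_bp(list(contig_id = "c", start = 1L, end = 10L),
                      list(contig_id = "c", start = 1L, end = 10L)), 0L)
  expect_equal(gap_bp(list(contig_id = "c", start = 1L, end = 10L),
                      list(contig_id = "c", start = 11L, end = 20L)), 0L)
  expect_error(gap_bp(list(contig_id = "c1", start = 1L, end = 10L),
                      list(contig_id = "c2", start = 50L, end = 60L)),
               "same contig")
})

test_that("chaining splits exactly when a gap exceeds the threshold", {
  fx <- worked_example("tgb10")$features$features
  expect_length(chain_contig(fx, 50000), 1)
  expect_length(chain_contig(fx, 20000), 2)  # the 24,980 bp gap splits

  two <- sort_tbl(cat_tbl(c("BGC", "DEFENSE_SYSTEM")))
  two$start <- c(1L, 60002L); two$end <- c(10000L, 61000L)
  # gap is 50,001: just over
  expect_length(chain_contig(two, 50000), 2)
  two$start[2] <- 60001L  # gap exactly 50,000: chains
  expect_length(chain_contig(two, 50000), 1)

  expect_length(chain_contig(fx[0, ], 50000), 0)
  expect_error(chain_contig(fx[c(2, 1, 3, 4), ], 50000), "sorted")
  expect_error(chain_contig(fx, -1), "positive")
})

test_that("island classes follow the category-set vocabulary exactly", {
  cases <- list(
    list(c("BGC", "DEFENSE_SYSTEM"), "defense-metabolite"),
    list(c("BGC", "CRISPR_ARRAY"), "CRISPR-metabolite"),
    list(c("BGC", "CAS_CLUSTER"), "Cas-metabolite"),
    list(c("BGC", "CRISPR_ARRAY", "CAS_CLUSTER"),
         "combined CRISPR-Cas-defense-metabolite"),
    list(c("CRISPR_ARRAY", "CAS_CLUSTER", "DEFENSE_SYSTEM", "BGC"),
         "combined CRISPR-Cas-defense-metabolite"),
    list(c("BGC", "CRISPR_ARRAY", "DEFENSE_SYSTEM"),
         "CRISPR-defense-metabolite"),
    list(c("BGC", "CAS_CLUSTER", "DEFENSE_SYSTEM"),
         "Cas-defense-metabolite"),
    list(c("BGC", "PROPHAGE"), "prophage-metabolite"),
    list(c("BGC", "PROPHAGE", "DEFENSE_SYSTEM"),
         "prophage-defensive-metabolic"),
    list(c("BGC", "PROPHAGE", "CRISPR_ARRAY"),
         "prophage-defensive-metabolic"),
    list(c("BGC", "PROPHAGE", "CAS_CLUSTER", "DEFENSE_SYSTEM"),
         "prophage-defensive-metabolic")
  )
  for (cs in cases) {
    expect_equal(classify_island(cs[[1]]), cs[[2]],
                 info = paste(cs[[1]], collapse = "+"))
    expect_true(cs[[2]] %in% island_classes())
    # pure function of the set: duplicates and order are irrelevant
    expect_equal(classify_island(rev(rep(cs[[1]], 2))), cs[[2]])
  }
  # not islands: no BGC anchor, or nothing but BGCs
  expect_true(is.na(classify_island("BGC")))
  expect_true(is.na(classify_island(c("BGC", "BGC"))))
  expect_true(is.na(classify_island(c("PROPHAGE", "DEFENSE_SYSTEM"))))
  expect_true(is.na(classify_island("CRISPR_ARRAY")))
  expect_error(classify_island(character(0)), "empty")
})

test_that("overlap records capture relation and width", {
  m <- sort_tbl(tibble::tibble(
    feature_id = c("bgc", "def"), genome_id = "g", contig_id = "c",
    start = c(100L, 400L), end = c(1000L, 600L),
    category = c("BGC", "DEFENSE_SYSTEM"), subtype = "", source = "t",
    strand = "unknown"
  ))
  ov <- detect_overlaps(m)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$relation, "contains")
  expect_equal(ov$overlap_bp, 201L)

  m$start <- c(1L, 5L); m$end <- c(10L, 20L)
  ov2 <- detect_overlaps(sort_tbl(m))
  expect_equal(ov2$relation, "partial")
  expect_equal(ov2$overlap_bp, 6L)

  m$start <- c(1L, 5L); m$end <- c(10L, 30000L)
  m2 <- m; m2$start <- c(1L, 100L); m2$end <- c(10L, 200L)
  expect_equal(nrow(detect_overlaps(sort_tbl(m2))), 0)

  m3 <- m; m3$start <- c(5L, 5L); m3$end <- c(20L, 20L)
  expect_equal(detect_overlaps(sort_tbl(m3))$relation, "identical")

  # contained_by: earlier, shorter feature inside a later-starting? no --
  # earlier feature contained in one that starts at the same base
  m4 <- m; m4$start <- c(5L, 5L); m4$end <- c(10L, 50L)
  expect_equal(detect_overlaps(sort_tbl(m4))$relation, "contained_by")
})

test_that("detector reproduces the bundled worked examples", {
  for (name in c("tgb10", "ibrc10908k", "oceanimonas")) {
    ex <- worked_example(name)
    isl <- detect_islands(ex$features)
    expect_equal(nrow(isl), 1, info = name)
    expect_equal(isl$island_class, ex$expected$island_class, info = name)
    expect_equal(isl$n_members, ex$expected$n_members, info = name)
    expect_equal(isl$gaps_bp[[1]], ex$expected$gaps_bp, info = name)
    expect_equal(isl$span_start, min(ex$features$features$start))
    expect_equal(isl$span_end, max(ex$features$features$end))
    expect_equal(isl$island_id, paste0(ex$features$genome_id, ":contig_1:1"))
  }
})

test_that("non-island clusters are dropped but recoverable", {
  tbl <- cat_tbl(c("BGC", "BGC", "DEFENSE_SYSTEM"))
  tbl$start <- c(1L, 2000L, 500000L)
  tbl$end <- tbl$start + 999L
  isl <- detect_islands(annotation_set(tbl), keep_nonislands = TRUE)
  expect_equal(nrow(isl), 0)
  non <- attr(isl, "non_islands")
  expect_equal(nrow(non), 2)
  expect_setequal(non$categories, c("BGC,BGC", "DEFENSE_SYSTEM"))
})

test_that("chaining equals the brute-force transitive closure", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample.int(25, 1)
    tbl <- sort_tbl(random_contig_tbl(n))
    thr <- sample(c(5000, 20000, 50000), 1)
    got <- canonical_partition(
      lapply(chain_contig(tbl, thr), function(cl) cl$feature_id))
    want <- brute_force_clusters(tbl, thr)
    expect_identical(got, want)
  }
})

test_that("detection is order-invariant and threshold-monotone", {
  set.seed(202)
  for (rep in 1:60) {
    tbl <- random_contig_tbl(sample.int(20, 1))
    isl <- detect_islands(annotation_set(tbl))
    # permutation invariance
    shuffled <- tbl[sample(nrow(tbl)), ]
    expect_identical(detect_islands(annotation_set(shuffled)), isl)
    # partition: chained clusters cover each feature exactly once
    clusters <- chain_contig(sort_tbl(tbl), 50000)
    expect_setequal(unlist(lapply(clusters, function(cl) cl$feature_id)),
                    tbl$feature_id)
    expect_equal(sum(vapply(clusters, nrow, integer(1))), nrow(tbl))
    # monotonicity: clusters at the smaller threshold nest in the larger
    small <- chain_contig(sort_tbl(tbl), 10000)
    big <- chain_contig(sort_tbl(tbl), 50000)
    for (cl in small) {
      container <- Filter(function(b) all(cl$feature_id %in% b$feature_id),
                          big)
      expect_length(container, 1)
    }
  }
})

test_that("multi-genome tables are processed per genome", {
  t1 <- worked_example("tgb10")$features$features
  t2 <- worked_example("oceanimonas")$features$features
  both <- dplyr::bind_rows(t1, t2)
  isl <- detect_islands(both)
  expect_equal(nrow(isl), 2)
  expect_setequal(isl$genome_id, c("TGB10", "GK1"))
  empty <- detect_islands(annotation_set(t1[0, ], genome_id = "g"))
  expect_equal(nrow(empty), 0)
})

test_that("island writers emit consistent TSV/JSON/GFF3", {
  isl <- detect_islands(worked_example("tgb10")$features)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_islands(isl, tsv, format = "tsv")
  write_islands(isl, js, format = "json")
  write_islands(isl, gff, format = "gff3")
  flat <- utils::read.delim(tsv)
  expect_equal(nrow(flat), 1)
  expect_equal(flat$n_members, 4)
  expect_equal(flat$max_gap_bp_observed, 24980)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(parsed$schema_version, "1.0")
  expect_length(parsed$islands, 1)
  expect_length(parsed$islands[[1]]$members, 4)
  glines <- readLines(gff)
  expect_true(any(grepl("genomic_island", glines)))
  expect_equal(sum(grepl("Parent=TGB10", glines)), 4)
})
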