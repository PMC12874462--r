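# Feature model and format harmonization.

tsv_header <- "genome_id\tcontig_id\tstart\tend\tcategory\tsubtype\tsource"

test_that("native TSV rows become validated 1-based features", {
  txt <- paste(
    tsv_header,
    "TGB10\tctg1\t657024\t657967\tCRISPR_ARRAY\tCRISPR\tCRISPRCasFinder",
    sep = "\n")
  set <- read_feature_table(textConnection(txt))
  expect_equal(set$genome_id, "TGB10")
  expect_equal(nrow(set$features), 1)
  expect_equal(set$features$start, 657024L)
  expect_equal(set$features$end, 657967L)
  expect_equal(set$features$category, "CRISPR_ARRAY")
  # deterministic auto id
  expect_equal(set$features$feature_id,
               "TGB10:ctg1:657024-657967:CRISPR_ARRAY")
})

test_that("empty input yields an empty annotation set", {
  set <- read_feature_table(textConnection(""), genome_id = "g")
  expect_equal(nrow(set$features), 0)
  set2 <- read_feature_table(textConnection(tsv_header), genome_id = "g")
  expect_equal(nrow(set2$features), 0)
})

test_that("malformed input is rejected with the offending line number", {
  bad_fields <- paste(
    tsv_header,
    "g\tc\t1\t10\tBGC\tx\tsrc",
    "g\tc\t5\tBGC",  # line 3: too few fields
    sep = "\n")
  expect_error(read_feature_table(textConnection(bad_fields)), "line 3")

  rev_coords <- paste(
    tsv_header,
    "g\tc\t100\t10\tBGC\tx\tsrc",
    sep = "\n")
  expect_error(read_feature_table(textConnection(rev_coords)),
               "start > end at line 2")

  bad_cat <- paste(
    tsv_header,
    "g\tc\t1\t10\tPLASMID\tx\tsrc",
    sep = "\n")
  expect_error(read_feature_table(textConnection(bad_cat)),
               "unknown category 'PLASMID' at line 2")

  non_num <- paste(
    tsv_header,
    "g\tc\tone\t10\tBGC\tx\tsrc",
    sep = "\n")
  expect_error(read_feature_table(textConnection(non_num)),
               "line 2")
})

test_that("BED ingest converts 0-based half-open to 1-based inclusive", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("ctg1\t0\t100\tx", p)
  set <- read_feature_table(p, dialect = "bed", genome_id = "g",
                            category = "BGC")
  expect_equal(set$features$start, 1L)
  expect_equal(set$features$end, 100L)
  expect_equal(set$features$subtype, "x")
  # name-encoded category variant
  writeLines("ctg1\t10\t20\tDEFENSE_SYSTEM:RM_Type_I", p)
  set2 <- read_feature_table(p, dialect = "bed", genome_id = "g")
  expect_equal(set2$features$category, "DEFENSE_SYSTEM")
  expect_equal(set2$features$subtype, "RM_Type_I")
  # genome_id is mandatory for BED
  expect_error(read_feature_table(p, dialect = "bed"), "genome_id")
})

test_that("native TSV and JSON round-trips are lossless", {
  fx <- worked_example("tgb10")$features
  for (fmt in c("native_tsv", "json")) {
    p <- withr::local_tempfile()
    write_features(fx, p, format = fmt)
    back <- read_feature_table(p, dialect = fmt)
    expect_equal(as.data.frame(back$features), as.data.frame(fx$features),
                 info = fmt)
    expect_equal(back$genome_id, fx$genome_id, info = fmt)
  }
})

test_that("GFF3 export carries category/subtype attributes and re-imports", {
  fx <- worked_example("oceanimonas")$features
  p <- withr::local_tempfile(fileext = ".gff3")
  write_features(fx, p, format = "gff3")
  lines <- readLines(p)
  expect_true(any(grepl("category=BGC", lines)))
  expect_true(any(grepl("subtype=NI-siderophore", lines)))
  back <- read_feature_table(p, dialect = "gff3")
  expect_equal(as.data.frame(back$features), as.data.frame(fx$features))
})

test_that("BED round-trip preserves coordinates exactly", {
  fx <- worked_example("ibrc10908k")$features
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_features(fx, p1, format = "bed")
  back <- read_feature_table(p1, dialect = "bed", genome_id = fx$genome_id)
  expect_equal(back$features$start, fx$features$start)
  expect_equal(back$features$end, fx$features$end)
  expect_equal(back$features$category, fx$features$category)
  write_features(back, p2, format = "bed")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("feature order is total and invariant under input permutation", {
  set.seed(42)
  tbl <- random_contig_tbl(20)
  a <- annotation_set(tbl)
  for (i in 1:5) {
    b <- annotation_set(tbl[sample(nrow(tbl)), ])
    expect_identical(a$features, b$features)
  }
})

test_that("merge_sources unions features and rejects conflicts", {
  a <- annotation_set(genomic_features("g1", "c1", 1, 10, "BGC",
                                       feature_id = "a"))
  b <- annotation_set(genomic_features("g1", "c1", 100, 200, "PROPHAGE",
                                       feature_id = "b"))
  m <- merge_sources(a, b)
  expect_equal(nrow(m$features), 2)
  expect_equal(m$features$feature_id, c("a", "b"))

  empty <- annotation_set(m$features[0, ], genome_id = "g1")
  expect_identical(merge_sources(a, empty)$features, a$features)

  dup <- annotation_set(genomic_features("g1", "c2", 5, 9, "BGC",
                                         feature_id = "a"))
  expect_error(merge_sources(a, dup), "duplicate feature_id")

  other <- annotation_set(genomic_features("g2", "c1", 1, 10, "BGC"))
  expect_error(merge_sources(a, other), "mixed genome_ids")
})

test_that("constructor invariants hold", {
  expect_error(genomic_features("g", "c", 0, 10, "BGC"), "1-based")
  expect_error(genomic_features("g", "c", 20, 10, "BGC"), "start > end")
  expect_error(genomic_features("g", "c", 1, 10, "ISLAND"),
               "unknown category")
  # duplicate spans get distinct deterministic ids
  f <- genomic_features("g", "c", c(1, 1), c(10, 10), c("BGC", "BGC"))
  expect_equal(sort(f$feature_id),
               c("g:c:1-10:BGC#1", "g:c:1-10:BGC#2"))
})
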