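# Synthetic survey generator: determinism, manifest consistency, and
# recovery of planted structure by each detector.

small_config <- function(seed) {
  sim_config(seed = seed, n_genomes = 2, contigs_per_genome = c(1, 2),
             n_prophages = 2, prophage_len_bp = c(12000, 20000),
             n_quality = 10)
}

test_that("a fixed seed reproduces outputs byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_survey(small_config(99), outdir = d1)
  simulate_survey(small_config(99), outdir = d2)
  files <- c("features.tsv", "prophages.fasta", "spacers.fasta",
             "quality.tsv", "manifest.json")
  expect_setequal(list.files(d1), files)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # and a different seed changes them
  d3 <- withr::local_tempdir()
  simulate_survey(small_config(100), outdir = d3)
  expect_false(identical(readLines(file.path(d1, "features.tsv")),
                         readLines(file.path(d3, "features.tsv"))))
})

test_that("the manifest refers only to emitted ids, consistently", {
  sim <- simulate_survey(small_config(3))
  man <- sim$manifest
  for (isl in man$islands) {
    expect_true(all(isl$member_ids %in% sim$features$feature_id))
    rows <- sim$features[match(isl$member_ids, sim$features$feature_id), ]
    expect_equal(unique(rows$genome_id), isl$genome_id)
    expect_equal(unique(rows$contig_id), isl$contig_id)
    expect_equal(rows$category, isl$member_categories)
    expect_equal(isl$span_start, min(rows$start))
    expect_equal(isl$span_end, max(rows$end))
    # detectability flag consistent with the recorded gaps
    expect_equal(isl$detectable, all(isl$gaps_bp <= man$max_gap_bp))
  }
  expect_true(all(man$spacer_hits$spacer_id %in% names(sim$spacers)))
  expect_true(all(man$spacer_hits$target_id %in% names(sim$prophages)))
  expect_true(all(man$decoy_spacer_ids %in% names(sim$spacers)))
  expect_false(any(man$decoy_spacer_ids %in% man$spacer_hits$spacer_id))
})

test_that("planted protospacers are embedded verbatim per the manifest", {
  sim <- simulate_survey(small_config(5))
  hits <- sim$manifest$spacer_hits
  expect_true(nrow(hits) >= 4)
  for (i in seq_len(nrow(hits))) {
    target <- sim$prophages[[hits$target_id[i]]]
    window <- substr(target, hits$position[i],
                     hits$position[i] + hits$match_len[i] - 1)
    spacer <- sim$spacers[[hits$spacer_id[i]]]
    expected <- if (hits$strand[i] == "+") spacer else
      reverse_complement(spacer)
    expect_equal(window, expected)
  }
})

test_that("prophage GC lands within 1% of the target", {
  sim <- simulate_survey(sim_config(seed = 21, n_genomes = 1,
                                    n_prophages = 4,
                                    prophage_len_bp = c(20000, 30000),
                                    gc_target_pct = 60, n_quality = 4))
  gc <- gc_percent(sim$prophages)
  expect_true(all(abs(gc - 60) <= 1))
  # per-phage targets recorded in the manifest are honoured too
  sim2 <- simulate_survey(small_config(22))
  gc2 <- gc_percent(sim2$prophages)
  targets <- unlist(sim2$manifest$prophage_gc_target[names(sim2$prophages)])
  expect_true(all(abs(gc2 - targets) <= 1))
})

test_that("triage ground truth is recovered exactly, including boundaries", {
  sim <- simulate_survey(sim_config(seed = 31, n_genomes = 1,
                                    n_prophages = 1, n_quality = 37))
  expect_true(all(c(69, 70, 90, 91) %in% sim$quality$score))
  expect_true(90 %in% sim$quality$completeness_pct)
  expect_true(5 %in% sim$quality$contamination_pct)
  rec <- triage_prophages(sim$quality)
  expect_equal(rec$triage_class, sim$manifest$triage$expected_class)
  expect_equal(rec$high_quality, sim$manifest$triage$expected_pass)
})

test_that("infeasible placements fail before emission", {
  tiny <- sim_config(seed = 1, n_genomes = 1, contigs_per_genome = c(1, 1),
                     contig_len_bp = c(1000, 1000),
                     planted_islands = list(
                       island_spec(c("BGC", "PROPHAGE"), 39414)),
                     n_background = 0, n_prophages = 1, n_quality = 2)
  expect_error(simulate_survey(tiny), "infeasible")
  # a gap that would reorder members is rejected too
  bad <- sim_config(seed = 1, n_genomes = 1, planted_islands = list(
    island_spec(c("BGC", "DEFENSE_SYSTEM"), -50000,
                member_len_bp = c(10000, 500))),
    n_background = 0, n_prophages = 1, n_quality = 2)
  expect_error(simulate_survey(bad), "start before")
})

test_that("decoy specs that would leave a residual island are refused", {
  ambiguous <- sim_config(seed = 1, n_genomes = 1, planted_islands = list(
    island_spec(c("BGC", "DEFENSE_SYSTEM", "DEFENSE_SYSTEM"),
                c(10, 60000))),
    n_background = 0, n_prophages = 1, n_quality = 2)
  expect_error(simulate_survey(ambiguous), "sub-segment")
})

test_that("detectors recover exactly the planted structure", {
  for (seed in c(41, 42, 43)) {
    sim <- simulate_survey(small_config(seed))
    isl <- detect_islands(sim$features,
                          survey_thresholds(max_gap_bp = sim$config$max_gap_bp))
    planted <- Filter(function(i) i$detectable, sim$manifest$islands)
    expect_equal(nrow(isl), length(planted))
    detected <- lapply(isl$members, function(m) sort(m$feature_id))
    for (p in planted) {
      idx <- which(vapply(detected, identical, logical(1),
                          sort(p$member_ids)))
      expect_length(idx, 1)
      expect_equal(isl$island_class[idx], p$island_class)
    }
    hits <- screen_spacers(
      tibble::tibble(spacer_id = names(sim$spacers),
                     sequence = unname(sim$spacers)),
      sim$prophages)
    expect_identical(as.data.frame(hits),
                     as.data.frame(sim$manifest$spacer_hits))
  }
})
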