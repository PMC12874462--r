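# Seeded synthetic survey generator. Emits annotation tables, prophage
# and spacer sequences and quality tables whose spatial/statistical
# structure matches what the detectors assume, together with a
# ground-truth manifest, so every pipeline stage can be validated
# end-to-end without any external data.

MANIFEST_SCHEMA_VERSION <- "1.0"

CATEGORY_LEN_RANGES <- list(
  BGC = c(5000L, 30000L),
  DEFENSE_SYSTEM = c(800L, 5000L),
  CRISPR_ARRAY = c(500L, 2000L),
  CAS_CLUSTER = c(5000L, 10000L),
  PROPHAGE = c(20000L, 60000L)
)

CATEGORY_SUBTYPES <- list(
  BGC = c("ectoine", "terpene", "T3PKS", "betalactone", "NI-siderophore",
          "hydrogen-cyanide", "lanthipeptide-class-iii"),
  DEFENSE_SYSTEM = c("RM_Type_I", "Hachiman", "AbiD", "Ceres", "Belisama",
                     "anti:ardc"),
  CRISPR_ARRAY = "CRISPR",
  CAS_CLUSTER = "cas_operon",
  PROPHAGE = "phage_region"
)

# Independent classification lookup used for ground-truth expectations.
# Deliberately a literal re-statement of the island vocabulary rather
# than a call into classify_island(), so recovery tests compare two
# separately written routes.
spec_class_lookup <- function(categories) {
  u <- unique(categories)
  if (!"BGC" %in% u || length(u) == 1) return(NA_character_)
  defensive <- intersect(u, c("CRISPR_ARRAY", "CAS_CLUSTER", "DEFENSE_SYSTEM"))
  if ("PROPHAGE" %in% u) {
    if (length(defensive)) return("prophage-defensive-metabolic")
    return("prophage-metabolite")
  }
  map <- c(
    "DEFENSE_SYSTEM" = "defense-metabolite",
    "CRISPR_ARRAY" = "CRISPR-metabolite",
    "CAS_CLUSTER" = "Cas-metabolite",
    "CAS_CLUSTER+CRISPR_ARRAY" = "combined CRISPR-Cas-defense-metabolite",
    "CAS_CLUSTER+CRISPR_ARRAY+DEFENSE_SYSTEM" =
      "combined CRISPR-Cas-defense-metabolite",
    "CRISPR_ARRAY+DEFENSE_SYSTEM" = "CRISPR-defense-metabolite",
    "CAS_CLUSTER+DEFENSE_SYSTEM" = "Cas-defense-metabolite"
  )
  unname(map[paste(sort(defensive), collapse = "+")])
}

#' Specify a planted island
#'
#' Describes one island to embed in a synthetic genome: the ordered
#' member categories and the intervening gap after each member.
#' Negative gaps plant deliberate overlaps/embeddings (the next member
#' starts inside the previous one); gaps just above the threshold plant
#' decoys that must not be recovered as islands.
#'
#' @param member_categories Ordered character vector of member
#'   categories.
#' @param gap_bp_list Integer vector of gaps between adjacent members
#'   (length `length(member_categories) - 1`); may be negative.
#' @param subtypes Optional subtype per member.
#' @param member_len_bp Optional fixed member lengths (bp); lengths are
#'   otherwise drawn from per-category ranges. Required in practice for
#'   negative gaps, where the overlap must not exceed the previous
#'   member's length.
#' @param genome,contig Optional fixed placement (1-based indices);
#'   `NA` means random.
#' @return List of class `"island_spec"`.
#' @export
#' @examples
#' island_spec(c("BGC", "PROPHAGE"), 39414)
island_spec <- function(member_categories, gap_bp_list, subtypes = NULL,
                        member_len_bp = NULL, genome = NA, contig = NA) {
  bad <- setdiff(member_categories, FEATURE_CATEGORIES)
  if (length(bad)) data_error("unknown category '", bad[1], "'")
  if (length(gap_bp_list) != length(member_categories) - 1) {
    data_error("gap_bp_list must have one entry per adjacent member pair")
  }
  if (!is.null(subtypes) && length(subtypes) != length(member_categories)) {
    data_error("subtypes must match member_categories in length")
  }
  if (!is.null(member_len_bp)) {
    if (length(member_len_bp) != length(member_categories) ||
        any(member_len_bp < 1)) {
      data_error("member_len_bp must give a positive length per member")
    }
    member_len_bp <- as.integer(member_len_bp)
  }
  structure(list(member_categories = member_categories,
                 gap_bp_list = as.integer(gap_bp_list),
                 subtypes = subtypes, member_len_bp = member_len_bp,
                 genome = genome, contig = contig),
            class = "island_spec")
}

#' Default planted-island specifications
#'
#' One spec per island architecture in the survey vocabulary, plus an
#' embedded-overlap case (a defense system fully inside a BGC) and a
#' just-over-threshold decoy pair that must not chain at 50 kb. Gaps for
#' the combined, prophage-metabolite and defense-metabolite cases use
#' the published worked-example distances.
#'
#' @param max_gap_bp Threshold the decoy should just exceed.
#' @return List of [island_spec()] objects.
#' @export
default_island_specs <- function(max_gap_bp = 50000) {
  list(
    island_spec(c("BGC", "DEFENSE_SYSTEM"), 27170,
                subtypes = c("NI-siderophore", "Belisama")),
    island_spec(c("CRISPR_ARRAY", "BGC"), 12000,
                subtypes = c("CRISPR", "lanthipeptide-class-iii")),
    island_spec(c("CAS_CLUSTER", "BGC"), 8000,
                subtypes = c("cas_operon", "T3PKS")),
    island_spec(c("CRISPR_ARRAY", "CAS_CLUSTER", "DEFENSE_SYSTEM", "BGC"),
                c(78, 10303, 24980),
                subtypes = c("CRISPR", "cas_operon", "Hachiman",
                             "hydrogen-cyanide")),
    island_spec(c("BGC", "PROPHAGE"), 39414,
                subtypes = c("lanthipeptide-class-iii", "phage_region")),
    island_spec(c("BGC", "PROPHAGE", "DEFENSE_SYSTEM"), c(15000, 9000),
                subtypes = c("terpene", "phage_region", "AbiD")),
    # embedded overlap: defense system completely inside a 20 kb BGC
    island_spec(c("BGC", "DEFENSE_SYSTEM"), -15000,
                subtypes = c("T3PKS", "gcu233"),
                member_len_bp = c(20000, 1200)),
    # decoy: one base beyond the threshold, must split into singletons
    island_spec(c("BGC", "DEFENSE_SYSTEM"), max_gap_bp + 1,
                subtypes = c("ectoine", "RM_Type_I"))
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic survey. The defaults emulate the scale
#' of the published study the toolkit was built around: 38 genomes,
#' eight prophage sequences, 37 score-bearing prophage predictions
#' with plantings on the 70/90 score and 90%/5% quality boundaries,
#' one planted island per architecture (plus overlap and decoy cases),
#' and 32 nt spacers (a typical CRISPR spacer length).
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical
#'   outputs.
#' @param n_genomes Number of synthetic genomes.
#' @param contigs_per_genome Integer range `c(lo, hi)`.
#' @param contig_len_bp Integer range for contig lengths.
#' @param planted_islands List of [island_spec()]s.
#' @param n_background Per-genome count of isolated background features
#'   (placed with separation above the gap threshold so they never
#'   chain into anything).
#' @param n_prophages Number of prophage sequences to emit.
#' @param prophage_len_bp Integer range for prophage lengths.
#' @param gc_target_pct Per-prophage GC target (scalar, recycled) or
#'   `NULL` to draw one per phage from 45--65%.
#' @param protospacers_per_prophage Planted protospacers per prophage.
#' @param n_decoy_spacers Spacers emitted but never planted (expected
#'   hit count zero).
#' @param spacer_len_nt Spacer length (default 32 nt).
#' @param n_quality Rows in the quality table.
#' @param max_gap_bp Chaining threshold the ground truth is computed
#'   against.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       n_genomes = 38,
                       contigs_per_genome = c(1, 3),
                       contig_len_bp = c(1500000, 4000000),
                       planted_islands = default_island_specs(max_gap_bp),
                       n_background = 3,
                       n_prophages = 8,
                       prophage_len_bp = c(30000, 60000),
                       gc_target_pct = NULL,
                       protospacers_per_prophage = 2,
                       n_decoy_spacers = 4,
                       spacer_len_nt = 32,
                       n_quality = 37,
                       max_gap_bp = 50000) {
  if (!is_scalar_number(seed)) data_error("seed must be a number")
  for (rng in list(contigs_per_genome, contig_len_bp, prophage_len_bp)) {
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 1) {
      data_error("ranges must be c(lo, hi) with 1 <= lo <= hi")
    }
  }
  if (n_genomes < 1) data_error("n_genomes must be >= 1")
  structure(list(
    seed = as.integer(seed), n_genomes = as.integer(n_genomes),
    contigs_per_genome = as.integer(contigs_per_genome),
    contig_len_bp = as.integer(contig_len_bp),
    planted_islands = planted_islands,
    n_background = as.integer(n_background),
    n_prophages = as.integer(n_prophages),
    prophage_len_bp = as.integer(prophage_len_bp),
    gc_target_pct = gc_target_pct,
    protospacers_per_prophage = as.integer(protospacers_per_prophage),
    n_decoy_spacers = as.integer(n_decoy_spacers),
    spacer_len_nt = as.integer(spacer_len_nt),
    n_quality = as.integer(n_quality),
    max_gap_bp = as.numeric(max_gap_bp)
  ), class = "sim_config")
}

rint <- function(n, lo, hi) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

random_gc_sequence <- function(len, gc_pct) {
  n_gc <- round(len * gc_pct / 100)
  bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), len - n_gc, replace = TRUE))
  paste(sample(bases), collapse = "")
}

#' Generate a synthetic survey with ground truth
#'
#' Produces, deterministically for a given seed, the full set of inputs
#' the pipeline consumes -- a multi-genome feature table with planted
#' islands and isolated background features, prophage sequences with
#' controlled GC and verbatim planted protospacers (forward or reverse
#' complement), a spacer set including never-planted decoys, and a
#' quality table spanning the triage boundaries -- plus a manifest
#' recording exactly what was planted and what the detectors are
#' expected to recover.
#'
#' Planted islands whose spec contains a gap above the threshold are
#' decoys: the generator verifies that no segment of such a spec could
#' itself classify as an island (and errors otherwise), so the ground
#' truth stays unambiguous. Background features are spaced more than
#' the threshold from everything else.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, writes `features.tsv`,
#'   `prophages.fasta`, `spacers.fasta`, `quality.tsv` and
#'   `manifest.json`.
#' @return List with `features` (tibble), `genomes` (contig table),
#'   `prophages` and `spacers` (named character vectors), `quality`
#'   (tibble) and `manifest` (list; see details in the JSON schema).
#' @export
#' @examples
#' sim <- simulate_survey(sim_config(seed = 7, n_genomes = 2,
#'                                   n_prophages = 2, n_quality = 8))
#' names(sim)
simulate_survey <- function(config = sim_config(), outdir = NULL) {
  if (!inherits(config, "sim_config")) {
    data_error("config must be built with sim_config()")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
          add = TRUE)
  set.seed(config$seed)

  genome_ids <- sprintf("sim%02d", seq_len(config$n_genomes))
  n_contigs <- rint(config$n_genomes, config$contigs_per_genome[1],
                    config$contigs_per_genome[2])
  genomes <- dplyr::bind_rows(lapply(seq_len(config$n_genomes), function(g) {
    tibble::tibble(
      genome_id = genome_ids[g],
      contig_id = sprintf("ctg%d", seq_len(n_contigs[g])),
      length_bp = rint(n_contigs[g], config$contig_len_bp[1],
                       config$contig_len_bp[2])
    )
  }))

  # assign each planted spec and each background feature to a contig
  specs <- config$planted_islands
  spec_genome <- vapply(specs, function(s) {
    if (is.na(s$genome)) sample.int(config$n_genomes, 1) else as.integer(s$genome)
  }, integer(1))
  spec_contig <- vapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    if (is.na(s$contig)) sample.int(n_contigs[spec_genome[i]], 1)
    else as.integer(s$contig)
  }, integer(1))

  groups <- list()
  for (i in seq_along(specs)) {
    groups[[length(groups) + 1]] <- list(kind = "island", idx = i,
                                         genome = spec_genome[i],
                                         contig = spec_contig[i])
  }
  for (g in seq_len(config$n_genomes)) {
    for (b in seq_len(config$n_background)) {
      groups[[length(groups) + 1]] <- list(
        kind = "background", idx = NA_integer_, genome = g,
        contig = sample.int(n_contigs[g], 1)
      )
    }
  }

  feature_rows <- list()
  manifest_islands <- list()
  counters <- stats::setNames(rep(0L, config$n_genomes), genome_ids)

  for (g in seq_len(config$n_genomes)) {
    for (k in seq_len(n_contigs[g])) {
      here <- Filter(function(gr) gr$genome == g && gr$contig == k, groups)
      if (!length(here)) next
      here <- here[sample(length(here))]
      contig_id <- sprintf("ctg%d", k)
      contig_len <- genomes$length_bp[genomes$genome_id == genome_ids[g] &
                                        genomes$contig_id == contig_id]
      cursor <- rint(1, 1, 10000)
      for (grp in here) {
        if (grp$kind == "island") {
          s <- specs[[grp$idx]]
          m <- length(s$member_categories)
          lens <- s$member_len_bp %||% vapply(s$member_categories, function(cat) {
            r <- CATEGORY_LEN_RANGES[[cat]]
            rint(1, r[1], r[2])
          }, integer(1))
          starts <- integer(m); ends <- integer(m)
          starts[1] <- cursor
          ends[1] <- starts[1] + lens[1] - 1L
          if (m > 1) {
            for (j in 2:m) {
              starts[j] <- ends[j - 1] + s$gap_bp_list[j - 1] + 1L
              if (starts[j] <= starts[j - 1]) {
                data_error("island spec ", grp$idx, ": gap ",
                           s$gap_bp_list[j - 1],
                           " makes member ", j, " start before member ",
                           j - 1)
              }
              ends[j] <- starts[j] + lens[j] - 1L
            }
          }
          subtypes <- s$subtypes %||% vapply(s$member_categories, function(cat) {
            sample(CATEGORY_SUBTYPES[[cat]], 1)
          }, character(1))
          ids <- character(m)
          for (j in seq_len(m)) {
            counters[g] <- counters[g] + 1L
            ids[j] <- sprintf("%s_f%03d", genome_ids[g], counters[g])
          }
          feature_rows[[length(feature_rows) + 1]] <- tibble::tibble(
            feature_id = ids, genome_id = genome_ids[g],
            contig_id = contig_id, start = starts, end = ends,
            category = s$member_categories, subtype = subtypes,
            source = "simulator", strand = "unknown"
          )
          run_end <- cummax(ends)
          eff_gaps <- if (m > 1) {
            as.integer(pmax(0, starts[-1] - run_end[-m] - 1))
          } else integer(0)
          detectable <- all(eff_gaps <= config$max_gap_bp)
          expected_class <- spec_class_lookup(s$member_categories)
          if (is.na(expected_class)) {
            data_error("island spec ", grp$idx,
                       ": member categories do not form an island")
          }
          if (!detectable) {
            # a decoy must not leave behind any smaller island
            seg <- cumsum(c(1L, as.integer(eff_gaps > config$max_gap_bp)))
            seg_classes <- vapply(split(s$member_categories, seg),
                                  spec_class_lookup, character(1))
            if (any(!is.na(seg_classes))) {
              data_error("island spec ", grp$idx, " has a gap above the ",
                         "threshold but a sub-segment would still ",
                         "classify as an island; adjust the spec")
            }
          }
          manifest_islands[[length(manifest_islands) + 1]] <- list(
            spec_index = grp$idx,
            genome_id = genome_ids[g],
            contig_id = contig_id,
            member_ids = ids,
            member_categories = s$member_categories,
            span_start = min(starts),
            span_end = max(ends),
            gaps_bp = eff_gaps,
            island_class = expected_class,
            detectable = detectable
          )
          cursor <- max(ends)
        } else {
          cat_b <- sample(FEATURE_CATEGORIES, 1)
          r <- CATEGORY_LEN_RANGES[[cat_b]]
          len <- rint(1, r[1], r[2])
          counters[g] <- counters[g] + 1L
          fid <- sprintf("%s_f%03d", genome_ids[g], counters[g])
          feature_rows[[length(feature_rows) + 1]] <- tibble::tibble(
            feature_id = fid, genome_id = genome_ids[g],
            contig_id = contig_id, start = cursor,
            end = cursor + len - 1L, category = cat_b,
            subtype = sample(CATEGORY_SUBTYPES[[cat_b]], 1),
            source = "simulator", strand = "unknown"
          )
          cursor <- cursor + len - 1L
        }
        # keep the next group strictly beyond chaining range
        cursor <- cursor + as.integer(config$max_gap_bp) + 1L + rint(1, 1, 20000)
      }
      used <- cursor - as.integer(config$max_gap_bp) - 1L
      if (used > contig_len) {
        data_error("planted elements need ", used, " bp but contig ",
                   genome_ids[g], ":", contig_id, " is only ", contig_len,
                   " bp; infeasible placement")
      }
    }
  }

  features <- if (length(feature_rows)) {
    sorted <- dplyr::bind_rows(feature_rows)
    sorted[order(sorted$genome_id, sorted$contig_id, sorted$start,
                 sorted$end, sorted$feature_id), ]
  } else {
    empty_feature_tbl()
  }

  # --- prophage sequences with planted protospacers ---
  phage_ids <- sprintf("phage%02d", seq_len(config$n_prophages))
  phage_len <- rint(config$n_prophages, config$prophage_len_bp[1],
                    config$prophage_len_bp[2])
  gc_targets <- if (is.null(config$gc_target_pct)) {
    round(stats::runif(config$n_prophages, 45, 65), 1)
  } else {
    rep_len(config$gc_target_pct, config$n_prophages)
  }
  prophages <- stats::setNames(vapply(seq_len(config$n_prophages), function(i) {
    random_gc_sequence(phage_len[i], gc_targets[i])
  }, character(1)), phage_ids)

  spacer_seqs <- character(0)
  hit_rows <- list()
  sp_counter <- 0L
  slen <- config$spacer_len_nt
  for (i in seq_len(config$n_prophages)) {
    used_windows <- list()
    for (k in seq_len(config$protospacers_per_prophage)) {
      sp_counter <- sp_counter + 1L
      sid <- sprintf("spacer%03d", sp_counter)
      spacer <- paste(sample(c("A", "C", "G", "T"), slen, replace = TRUE),
                      collapse = "")
      strand <- sample(c("+", "-"), 1)
      pos <- NA_integer_
      for (try in 1:200) {
        cand <- rint(1, 1, phage_len[i] - slen + 1L)
        clash <- any(vapply(used_windows, function(w) {
          cand <= w[2] && (cand + slen - 1L) >= w[1]
        }, logical(1)))
        if (!clash) { pos <- cand; break }
      }
      if (is.na(pos)) data_error("could not place protospacer in ", phage_ids[i])
      used_windows[[length(used_windows) + 1]] <- c(pos, pos + slen - 1L)
      planted <- if (strand == "+") spacer else reverse_complement(spacer)
      seq_i <- prophages[[phage_ids[i]]]
      substr(seq_i, pos, pos + slen - 1L) <- planted
      prophages[[phage_ids[i]]] <- seq_i
      spacer_seqs[[sid]] <- spacer
      hit_rows[[length(hit_rows) + 1]] <- tibble::tibble(
        spacer_id = sid, target_id = phage_ids[i],
        position = as.integer(pos), strand = strand,
        match_len = as.integer(slen)
      )
    }
  }
  for (d in seq_len(config$n_decoy_spacers)) {
    sp_counter <- sp_counter + 1L
    spacer_seqs[[sprintf("spacer%03d", sp_counter)]] <-
      paste(sample(c("A", "C", "G", "T"), slen, replace = TRUE), collapse = "")
  }
  planted_hits <- if (length(hit_rows)) {
    h <- dplyr::bind_rows(hit_rows)
    h[order(h$spacer_id, h$target_id, h$position, h$strand), ]
  } else {
    tibble::tibble(spacer_id = character(0), target_id = character(0),
                   position = integer(0), strand = character(0),
                   match_len = integer(0))
  }

  # --- quality table spanning the triage boundaries ---
  nq <- config$n_quality
  score <- rep(NA_real_, nq)
  forced <- c(69, 70, 90, 91)
  n_forced <- min(4L, nq)
  score[seq_len(n_forced)] <- forced[seq_len(n_forced)]
  rest <- setdiff(seq_len(nq), seq_len(n_forced))
  n_unscored <- min(3L, length(rest))
  scored_rest <- if (length(rest) > n_unscored) {
    rest[seq_len(length(rest) - n_unscored)]
  } else integer(0)
  score[scored_rest] <- sample(40:100, length(scored_rest), replace = TRUE)
  completeness <- round(stats::runif(nq, 70, 100), 1)
  contamination <- round(stats::runif(nq, 0, 10), 1)
  if (nq >= 1) completeness[1] <- 90.0  # exactly on the gate: must fail
  if (nq >= 2) contamination[2] <- 5.0  # exactly on the gate: must fail
  qgenome <- genome_ids[rint(nq, 1, config$n_genomes)]
  qstart <- rint(nq, 1, 1000000)
  quality <- tibble::tibble(
    prophage_id = sprintf("pred%03d", seq_len(nq)),
    genome_id = qgenome,
    contig_id = "ctg1",
    start = qstart,
    end = qstart + rint(nq, 15000, 60000),
    score = score,
    completeness_pct = completeness,
    contamination_pct = contamination
  )
  # ground-truth triage, restated independently of classify_score()
  expected_class <- ifelse(is.na(score), "unscored",
                      ifelse(score < 70, "incomplete",
                        ifelse(score <= 90, "questionable", "intact")))
  expected_pass <- completeness > 90 & contamination < 5

  manifest <- list(
    schema_version = MANIFEST_SCHEMA_VERSION,
    seed = config$seed,
    max_gap_bp = config$max_gap_bp,
    islands = manifest_islands,
    spacer_hits = planted_hits,
    decoy_spacer_ids = if (config$n_decoy_spacers > 0) {
      sprintf("spacer%03d",
              seq(sp_counter - config$n_decoy_spacers + 1L, sp_counter))
    } else character(0),
    prophage_gc_target = stats::setNames(as.list(gc_targets), phage_ids),
    triage = tibble::tibble(
      prophage_id = quality$prophage_id,
      expected_class = expected_class,
      expected_pass = expected_pass
    )
  )

  out <- list(features = features, genomes = genomes,
              prophages = prophages, spacers = unlist(spacer_seqs),
              quality = quality, manifest = manifest, config = config)
  if (!is.null(outdir)) write_simulation(out, outdir)
  out
}

write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tbl <- sim$features[, c("genome_id", "contig_id", "start", "end",
                          "category", "subtype", "source", "strand",
                          "feature_id")]
  atomic_write(file.path(outdir, "features.tsv"), function(p) {
    utils::write.table(tbl, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
  atomic_write(file.path(outdir, "prophages.fasta"), function(p) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$prophages), p)
  })
  atomic_write(file.path(outdir, "spacers.fasta"), function(p) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$spacers), p)
  })
  atomic_write(file.path(outdir, "quality.tsv"), function(p) {
    utils::write.table(sim$quality, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
  })
  atomic_write(file.path(outdir, "manifest.json"), function(p) {
    jsonlite::write_json(sim$manifest, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  })
  invisible(outdir)
}
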