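# Bundled worked examples: small feature tables with coordinates taken
# from published island architectures in a survey of aquatic bacterial
# strains, together with the islands they are expected to yield. They
# double as end-to-end fixtures and as documentation of the island
# vocabulary.

WORKED_EXAMPLES <- list(
  # S. proteolyticus TGB10: CRISPR array + Cas cluster + Hachiman
  # components + hydrogen-cyanide BGC on one contig; member gaps
  # 78, 10,303 and 24,980 bp, all within 50 kb, so the four elements
  # chain into a single combined CRISPR-Cas-defense-metabolite island.
  tgb10 = list(
    genome_id = "TGB10",
    rows = list(
      list(657024L, 657967L, "CRISPR_ARRAY", "CRISPR", "CRISPRCasFinder"),
      list(658046L, 666649L, "CAS_CLUSTER", "cas_operon", "CRISPRCasFinder"),
      list(676953L, 680635L, "DEFENSE_SYSTEM", "Hachiman", "DefenseFinder"),
      list(705616L, 718582L, "BGC", "hydrogen-cyanide", "antiSMASH")
    ),
    expected = list(island_class = "combined CRISPR-Cas-defense-metabolite",
                    n_members = 4L, gaps_bp = c(78L, 10303L, 24980L))
  ),
  # S. proteolyticum IBRC-M 10908K: lanthipeptide-class-III BGC and a
  # prophage 39,414 bp apart -> one prophage-metabolite island.
  ibrc10908k = list(
    genome_id = "IBRC-M_10908K",
    rows = list(
      list(3415756L, 3438299L, "BGC", "lanthipeptide-class-iii", "antiSMASH"),
      list(3477714L, 3537879L, "PROPHAGE", "Ph_Salpro4", "PHASTEST")
    ),
    expected = list(island_class = "prophage-metabolite",
                    n_members = 2L, gaps_bp = 39414L)
  ),
  # Oceanimonas sp. GK1: NI-siderophore BGC adjacent (27,170 bp) to a
  # Belisama defense system -> one defense-metabolite island.
  oceanimonas = list(
    genome_id = "GK1",
    rows = list(
      list(746012L, 777519L, "BGC", "NI-siderophore", "antiSMASH"),
      list(804690L, 805508L, "DEFENSE_SYSTEM", "Belisama", "DefenseFinder")
    ),
    expected = list(island_class = "defense-metabolite",
                    n_members = 2L, gaps_bp = 27170L)
  )
)

#' Bundled island worked examples
#'
#' Returns one of three small single-contig feature tables with known
#' expected island calls (see the source for the architectures):
#' `"tgb10"` (four elements chaining into a combined
#' CRISPR-Cas-defense-metabolite island), `"ibrc10908k"` (BGC +
#' prophage, prophage-metabolite) and `"oceanimonas"` (BGC + defense
#' system, defense-metabolite).
#'
#' @param name Example name.
#' @return List with `features` (an [annotation_set()]) and `expected`
#'   (list with `island_class`, `n_members`, `gaps_bp`).
#' @export
#' @examples
#' ex <- worked_example("ibrc10908k")
#' detect_islands(ex$features)$island_class
worked_example <- function(name = c("tgb10", "ibrc10908k", "oceanimonas")) {
  name <- match.arg(name)
  ex <- WORKED_EXAMPLES[[name]]
  rows <- ex$rows
  tbl <- genomic_features(
    genome_id = ex$genome_id,
    contig_id = "contig_1",
    start = vapply(rows, function(r) r[[1]], integer(1)),
    end = vapply(rows, function(r) r[[2]], integer(1)),
    category = vapply(rows, function(r) r[[3]], character(1)),
    subtype = vapply(rows, function(r) r[[4]], character(1)),
    source = vapply(rows, function(r) r[[5]], character(1))
  )
  list(features = annotation_set(tbl, genome_id = ex$genome_id),
       expected = ex$expected)
}

#' Example prophage summary records
#'
#' The eight high-quality prophages of an aquatic-bacteria survey with
#' their published genome lengths (kbp), GC contents (%), lifestyles
#' and taxonomic assignments, as a ready-made input for
#' [summarize_prophages()].
#'
#' @return Tibble with one row per prophage.
#' @export
#' @examples
#' summarize_prophages(example_prophages())
example_prophages <- function() {
  tibble::tibble(
    prophage_id = c("Ph_Alpe", "Ph_Ocea", "Ph_Salpro1", "Ph_Salpro2",
                    "Ph_Salpro3", "Ph_Salpro4", "Ph_Sapr1", "Ph_Sapr2"),
    host = c("A. persicus", "Oceanimonas sp. GK1",
             "S. proteolyticum IBRC-M 10908",
             "S. proteolyticum IBRC-M 10908",
             "S. proteolyticum IBRC-M 10908",
             "S. proteolyticum IBRC-M 10908K",
             "S. proteolyticus 19052", "S. proteolyticus TGB10"),
    length_kbp = c(43.5, 38.4, 60.1, 60.6, 36.9, 60.1, 44.2, 59.5),
    gc_pct = c(39.81, 58.25, 62.84, 63.05, 65.63, 62.84, 51.82, 46.69),
    lifestyle = c("temperate", "temperate", "temperate", "temperate",
                  "temperate", "temperate", "virulent", "temperate"),
    taxon = c("Caudoviricetes", "Bielevirus phiO18P", "Arquatrovirinae",
              "Arquatrovirinae", "Streptomyces phage Chymera",
              "Arquatrovirinae", "Caudoviricetes", "Caudoviricetes")
  )
}
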