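Package: islescan
Title: Multi-Functional Genomic Island Detection in Bacterial Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for surveying annotated bacterial genomes for
    multi-functional genomic islands that co-localize biosynthetic gene
    clusters with defensive elements. Harmonizes heterogeneous annotation
    tables (TSV, BED, GFF3) into a validated per-genome feature set, chains
    same-contig features whose intervening gaps stay within a configurable
    threshold (50 kb by default), classifies the resulting islands
    (defense-, CRISPR-, Cas-, prophage- and combined metabolite
    architectures) and records coordinate overlaps between members.
    Also provides prophage quality triage on completeness scores and
    CheckV-style completeness/contamination gates, exact full-length
    CRISPR spacer-to-protospacer screening on both strands, survey-level
    count tables and circular-plot exports, and a seeded synthetic
    annotation generator with a ground-truth manifest for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    jsonlite,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
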