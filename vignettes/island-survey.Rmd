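---
title: "Detecting multi-functional genomic islands in annotated bacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multi-functional genomic islands in annotated bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islescan)
```

## The question islescan answers

Bacteria from extreme environments often pack metabolically expensive
assets — biosynthetic gene clusters (BGCs) for osmolytes, siderophores,
antimicrobials — next to the machinery that protects them: CRISPR-Cas
loci, restriction-modification and other defense systems, and
integrated prophages. `islescan` takes the *coordinates* of such
elements, as produced by upstream annotators (antiSMASH,
DefenseFinder, CRISPRCasFinder, PHASTEST, VirSorter2, ...), and asks a
purely spatial question: which of them cluster tightly enough on the
same contig to constitute one multi-functional genomic island, and of
which architecture?

The package does not predict any element from sequence. Its inputs are
harmonized feature tables; its contribution is the proximity rule, the
island vocabulary, the prophage quality triage, the exact
spacer-to-protospacer screen, and the survey summaries — plus a seeded
synthetic generator that makes the whole pipeline testable without any
external download.

## The island model

An island is a chain of annotated elements satisfying two criteria:

1. all members lie on the **same contig** (islands never span assembly
   gaps), and
2. the **intervening distance** between any two adjacent members is at
   most `max_gap_bp` = 50,000 bp by default, a range in which
   functional interactions between defense-related elements are
   commonly reported.

plus an anchoring requirement: a cluster only counts as an island when
it contains **at least one BGC and at least one non-BGC element**.
Chains of defense systems alone, or of BGCs alone, are reported
separately as non-island clusters.

### Gap arithmetic

For features $a$ before $b$ in `(start, end, feature_id)` order the
gap is the number of bases strictly between the spans,

$$g(a, b) = \max(0,\; \mathrm{start}_b - \mathrm{end}_a - 1),$$

so overlapping or abutting features have gap 0 and chain
unconditionally. A member whose gap satisfies $g \le 50{,}000$ joins
the open cluster; $g = 50{,}001$ starts a new one. The published
worked examples all reproduce under this convention (gaps 78, 10,303
and 24,980 bp in the four-element region below; 39,414 bp in the
BGC-prophage pair; 27,170 bp in the BGC-defense pair).

One deliberate refinement: during chaining the gap is measured to the
**running maximum end** of the open cluster, not only to the
immediately preceding feature. For non-nested annotations — including
every bundled worked example — the two definitions coincide. When one
feature is embedded in another (which real overlap cases like a
defense system inside a BGC do produce), the running-maximum form
makes the partition equal to the transitive closure of the pairwise
gap relation, so the result is independent of how ties and nestings
order the members. The recorded per-member `gaps_bp` use the same
convention, which keeps the invariant that every recorded gap is at
most the threshold. Ties on identical `(start, end)` are broken by
`feature_id`, making member order and island ids reproducible.

### Classification

The island class is a pure function of the set of member categories
(M = BGC, P = prophage, C = CRISPR array, A = Cas cluster, D = other
defense system; anti-defense systems are ingested as D with an
`anti:` subtype prefix):

| member categories            | label                                      |
|------------------------------|--------------------------------------------|
| M + D                        | defense-metabolite                         |
| M + C                        | CRISPR-metabolite                          |
| M + A                        | Cas-metabolite                             |
| M + C + A (± D)              | combined CRISPR-Cas-defense-metabolite     |
| M + P                        | prophage-metabolite                        |
| M + P + any of C/A/D         | prophage-defensive-metabolic               |
| M + C + D                    | CRISPR-defense-metabolite                  |
| M + A + D                    | Cas-defense-metabolite                     |

The first six labels reproduce the vocabulary used in published
surveys of this kind; the last two are compound labels for
combinations such surveys name as models but do not exhibit, defined
here so that classification stays total and deterministic on unseen
data.

Coordinate overlaps between members are always recorded (relation
`partial`, `contains`, `contained_by` or `identical`, with the overlap
width in bp), because embedded annotations — a defense system wholly
inside a BGC, a segment shared by two operons — are biologically the
most tightly integrated cases and must not be silently merged or
dropped. Whether an overlapping segment "belongs" to one element or
both is a question the data cannot answer; the overlap record
preserves the information without deciding.

```{r}
ex <- worked_example("tgb10")
islands <- detect_islands(ex$features)
flatten_islands(islands)
islands$gaps_bp[[1]]
```

## Prophage triage

Two independent decision rules, both configurable through
`survey_thresholds()`:

* **Completeness-score classes** (PHASTEST scale): score < 70 is
  `incomplete`, 70 ≤ score ≤ 90 `questionable`, score > 90 `intact`.
  Both boundary values belong to `questionable`. Records with no score
  (e.g. VirSorter2 calls) are classed `unscored` and excluded from
  score tallies rather than rejected.
* **High-quality gate** (CheckV-style estimates): completeness
  **strictly greater** than 90% *and* contamination **strictly less**
  than 5%. The strictness follows the wording of the rule the package
  implements ("more than", "less than"); a record at exactly 90.0/5.0
  fails. Users who prefer inclusive boundaries can shift the
  thresholds by an epsilon.

Summary statistics (`summarize_prophages()`) are plain arithmetic
means and extrema, reported at full precision. Published tables often
truncate rather than round (56.366% printed as 56.36%), so comparisons
against printed values should allow ±0.01 on percentages.

Deduplication of overlapping calls from different predictors is *not*
part of the triage rules: `collapse_overlapping_prophages()` is
provided as an optional utility with a pragmatic 50% reciprocal
overlap default, but that fraction is a convenience, not a published
value, and the default pipeline never invokes it.

## Spacer screening

A spacer hits a prophage only with a **perfect, full-length,
zero-mismatch** match, on either strand. This is implemented as exact
string matching rather than alignment: with exactness required, an
e-value cutoff of $10^{-4}$ cannot reject any full-length hit on
realistic target sizes (a 20-nt exact match in a 100-kb target has an
expectation around $10^{-7}$), so the e-value is recorded in
`survey_thresholds()` for documentation but never computed.

Conventions worth knowing:

* `N` never matches, on either side — an ambiguous base is not
  evidence of identity.
* Overlapping occurrences are all reported.
* For a palindromic spacer (equal to its reverse complement) the
  reverse-complement occurrence is the same physical match and is
  reported once, on the forward strand.
* Hit positions are 1-based starts on the target's forward strand,
  whatever the strand of the match.

## The synthetic survey generator

Because the kind of survey this package supports typically deposits no
reusable accessions, validation rests on `simulate_survey()`: a seeded
generator that emits the complete input bundle (multi-genome feature
TSV, prophage FASTA, spacer FASTA, quality TSV) together with a
manifest of ground truth. Its defaults mirror the scale of the survey
the toolkit was built around — 38 genomes, 8 prophage sequences, 37
score-bearing predictions, one planted island per architecture — and
its structural guarantees are what make recovery testing meaningful:

* background features are spaced more than the gap threshold from
  everything, so they can never chain into a planted island;
* planted gaps may sit just below or above the 50-kb boundary, and
  negative gaps plant genuine overlaps and embeddings;
* a spec with an over-threshold gap is a *decoy*, and the generator
  refuses decoys whose fragments would still classify as islands, so
  the expected result is always unambiguous;
* protospacers are embedded verbatim (forward or reverse complement),
  at positions recorded in the manifest; decoy spacers are emitted but
  never planted;
* prophage sequences hit their GC target within rounding (the G+C
  count is fixed, not sampled), and spacers default to 32 nt, a
  typical CRISPR spacer length;
* the expected island class in the manifest comes from a lookup table
  written independently of `classify_island()`, so recovery tests
  compare two separately authored routes.

What the generator does **not** emulate: real gene content, BGC
architecture, codon usage, assembly artefacts, or annotation error.
Passing recovery tests therefore demonstrates that the detectors
faithfully implement their stated rules on data with the assumed
spatial structure — not that upstream annotations are accurate, nor
that the 50-kb rule is biologically optimal.

```{r}
sim <- simulate_survey(sim_config(seed = 7, n_genomes = 2,
                                  n_prophages = 2, n_quality = 8))
detect_islands(sim$features)$island_class
length(Filter(function(i) i$detectable, sim$manifest$islands))
```

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere internally,
  matching how annotation reports print spans; BED's 0-based
  half-open convention is converted at the boundary.
* **Sorting** is total: `(contig_id, start, end, feature_id)`. All
  results are invariant under permutation of input rows.
* **Auto ids** are deterministic
  (`genome:contig:start-end:category`, with `#k` suffixes for exact
  duplicates) and assigned in coordinate order.
* **Percentages** are stored at full precision and only rounded (half
  away from zero, two decimals) at display time by `format_pct()`.
* **Linked multi-gene components** (e.g. the two Hachiman genes HamB
  and HamA_2 annotated as one span) are taken exactly as the input
  rows give them: each row is one element, and suppliers may merge or
  split such components upstream; island membership is unaffected
  either way as long as the components are within the gap threshold.
* **Hybrid BGCs** are single features with comma-joined subtype
  lists; `tally_bgc()` makes the double-counting explicit by emitting
  both a per-component-class table and a hybrid-combination table,
  since surveys report both views.
* **Degenerate inputs**: empty tables are valid everywhere and
  produce empty, correctly-typed results; malformed rows fail with
  the input line number; infeasible synthetic placements fail before
  any file is written.

## Problem sizes used by the test suite

The bundled suite validates the oracle equivalences and recovery
guarantees at sizes chosen to exercise every code path while keeping a
full run under a minute on one CPU: 1,000 random contigs of up to 25
features for the chaining-versus-brute-force check, 250 contigs for
monotonicity and order invariance, 100 seeded synthetic genomes for
island recovery (including overlap and decoy plantings), and 100
replicates of planted-protospacer recovery on ≥10-kb targets plus 60
random-sequence comparisons against a naive sliding-window scan for
the spacer screen.

## Limitations

* Island calls are only as good as the upstream annotations; the
  package validates coordinates, not biology.
* The 50-kb rule is a single global threshold; no attempt is made to
  model local gene density or operon structure.
* Spacer screening is exact by design: degenerate or partial
  protospacer matches and PAM context are out of scope.
* The survey tallies treat each input row as one record; reconciling
  double-annotated segments across tools is left to the overlap
  records and the user.
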