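---
title: "Local haplotype analysis: model, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local haplotype analysis: model, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localhap)
```

## The model

A sequenced tissue is modeled as a mixture of cell lineages, each
contributing a local haplotype with some proportion. Every sequencing
fragment (a read or a read pair) derives from one DNA molecule and therefore
from exactly one haplotype. Where two or three heterozygous SNPs lie close
enough for one fragment to span them — a *block* — the bases a fragment
shows at those positions are a direct, assumption-free observation of one
haplotype. A uniform diploid genome admits at most two haplotypes per block;
a third is evidence of genomic heterogeneity at that locus that no
site-by-site genotype model can see.

Observation is one-sided: fragments that fail to span multiple SNPs reveal
nothing, so the observed haplotype count is a *lower bound* on the
underlying count (never an over-count, barring sequencing or mapping error),
and it grows with depth of coverage as more fragments happen to span the
block. The 0- and 1-haplotype categories in the summary tables quantify this
under-observation; they are not evidence of homozygosity, since both SNPs in
a block were called heterozygous.

## Parameters and their defaults

| parameter | default | units | why |
|---|---|---|---|
| `max_span` | 500 | bases | the region one fragment can plausibly span with typical short-read libraries; blocks are runs of ≥ 2 het SNPs within `max_span` of the run's first SNP |
| `min_mapq` | 30 | Phred | ≤ 1/1000 probability of misplacement; reads below it contribute nothing |
| `min_baseq` | 30 | Phred | ≤ 1/1000 base-call error; a lower-quality base means the read *skipped* that SNP |
| `min_support` | 3 | fragments | a pattern seen fewer than three times is not believed |
| `exact_cap` | 3 | SNPs | largest block size handled by the exhaustive minimum-cover solver |

The support rule applies to literal read-based patterns *before* clustering
(so `AG_` and `AGA` are counted separately for support), and never to
clustered haplotypes — a clustered haplotype may rest on two patterns of
three fragments each. This ordering mirrors the filter cascade's intent:
noisy observations are removed first, parsimony reasons over what survives.

## Parsimonious clustering

Two patterns are *compatible* when they share at least one covered position
and agree everywhere both are covered. Compatibility deliberately requires
overlap: `A_` and `_G` on a 2-SNP block carry no mutual phase evidence, and
fusing them would fabricate a haplotype no fragment supports. Merging is the
position-wise union (`CG_` + `_GA` → `CGA`).

Two solvers are provided:

* `minimum_haplotype_cover()` — the reference. Candidate complete haplotypes
  are the per-position products of *observed* alleles only (a completion
  never introduces a base no read showed), and subsets are enumerated in
  increasing size, so the reported minimum is exact and
  permutation-invariant; among minima the lexicographically smallest witness
  is returned, making outputs reproducible. At 2–3 SNPs the candidate space
  is at most a few dozen haplotypes, so exhaustive search is instant and an
  ILP/SAT formulation would be over-engineering.
* `greedy_cluster()` — a single-pass agglomeration processing patterns in
  descending support (ties broken lexicographically), merging each into the
  first compatible cluster. Greedy agglomeration is order-sensitive, and no
  canonical order exists for it, so the order is fixed and documented, the
  greedy count is reported alongside the exact one, and the exact solver is
  what classification uses for 2–3-SNP blocks. Blocks of 4+ SNPs are
  detected and reported with their pattern counts, but their haplotype count
  falls back to the greedy cluster count and they are excluded from the 2-
  and 3-SNP summary tables; a sound statistical treatment of their partial
  patterns is out of scope here.

For 2-SNP blocks every phase-informative pattern is complete, so the
observed haplotype count is simply the number of distinct complete patterns;
for 3-SNP blocks it is the exact parsimony minimum.

## Fragment bookkeeping

* Coordinates are 0-based half-open internally (the alignment-API
  convention); all outputs print 1-based positions.
* Fragments covering fewer than two SNP positions carry no phase
  information and never form patterns, but they stay in `total_fragments`,
  which keeps a well-covered-but-never-spanned (0-haplotype) block
  distinguishable from a block with no usable coverage at all.
* If both mates of a pair cover the same SNP and agree, the base counts once
  (a fragment, not a read, is the unit of observation). If they disagree,
  the fragment skips that position — the most conservative local action; no
  global fragment rejection is attempted.
* A pattern assembled from both mates with no single read covering all its
  positions is flagged *pair-bridged* (`pattern_bridged_counts` in the block
  table); such fragments are admitted, since a read pair is one molecule.
* Bases outside the called REF/ALT set are retained by default
  (`drop_noncalled = FALSE`): anomalous alleles are rare but real, and
  blocks exceeding the called-allele haplotype bound are part of what the
  method can reveal. Duplicate handling trusts the BAM duplicate flag; no
  in-tool deduplication is attempted.

## Block building

"Within 500 bases of each other" is ambiguous for runs of 3+ SNPs (pairwise?
consecutive gaps? total span?). The default anchors the span at the block's
first SNP — every member lies within `max_span` of it, so a fragment of that
span can physically cover the whole block — with a SNP exactly `max_span`
away included. `span` is reported as the first-to-last distance, which is
therefore ≤ `max_span` by construction. The consecutive-gap rule
(`rule = "gap"`) is available for sensitivity analysis; it produces longer
blocks whose ends can be unspannable. The greedy left-to-right partition is
asserted as this tool's block definition: blocks are disjoint in SNP
membership and a re-run is bit-identical.

## The simulator

`truth_spec()` describes a short reference segment, planted SNP offsets, a
haplotype mixture with proportions, and the sequencing regime: mean per-base
read depth (fragment count = `depth × segment / (2 × read length)`),
paired-end geometry (uniform fragment placement, Gaussian insert), a
constant-or-mixed Phred quality model, constant MAPQ, and a uniform
substitution error rate. `simulate_sample()` writes a sorted indexed BAM,
a matched VCF and a plain-text truth table, byte-reproducible for a fixed
seed. Reads are written pre-aligned (their positions are known by
construction), keeping tests hermetic; MAPQ is asserted, not computed.

Every planted SNP is emitted as a heterozygous VCF record even when the
planted mixture is degenerate (one haplotype): the VCF emulates *caller
output consumed as input*, and taking it at face value is exactly what the
pipeline does with real callers — this is what makes 0/1-haplotype blocks
reproducible in tests.

What the simulator does **not** emulate: GC or mappability bias, indels,
mapping ambiguity from segmental duplications (the segdup question is
handled by interval annotation, not simulation), or realistic quality-score
distributions. Passing tests therefore demonstrate the *logic* of the
pipeline — filtering, pattern extraction, clustering, classification — on an
idealized read generator; they do not certify behavior under real mapping
artifacts.

The fixed worked-example fixtures use deliberately simple geometry: the
2-SNP fixture plants SNPs 300 bases apart with 100-bp paired reads (~400-bp
insert), so every fragment bridges the SNPs through its mates, as a
2012-era whole-genome library would; the 3-SNP fixture produces its partial
patterns (`CG_`, `_GA`) purely from fragment geometry.

## Numerical and degenerate-input choices

* Ties in the exact solver resolve to the lexicographically smallest witness
  set; ties in greedy ordering resolve by pattern string. No randomness
  anywhere in the analysis path.
* Empty inputs degrade gracefully: no het SNPs → header-only outputs; a
  chromosome absent from the BAM header → empty result with a warning
  (a missing index, unknown sample, unsorted VCF or malformed BED line are
  hard errors).
* Percentages in frequency tables are rounded at a configurable number of
  decimals (0 by default); raw counts are always emitted so rounding never
  hides data, and category counts always sum to the total.
* When a block overlaps several gene-feature sets, `feature_category()`
  assigns one label by caller-specified precedence (e.g. exonic > intronic >
  intergenic), since the categories are usually wanted mutually exclusive;
  interval sets are user-named rather than hard-coded.

## Problem sizes used by the test suite

Property tests run the full simulate → BAM → extract → cluster path on a
400–500-base segment: 50 seeds across depths {5, 10, 20, 40, 80} for the
under-observation property (observed ≤ planted; mean observed non-decreasing
in depth), 100 replicates × mixtures of 1–4 planted haplotypes at depth 200
for exact recovery, and 200+ random pattern sets for greedy-vs-exact oracle
equivalence. These sizes give stable statistics while keeping the whole
suite in the minutes range on a laptop.

## Known limitations

* Haplotype counts are lower bounds; comparisons across samples with
  different depths are confounded by under-observation.
* The method inherits whatever biases the upstream SNP caller has — blocks
  exist only around called heterozygous SNPs.
* Mapping artifacts (paralog collapse) can fabricate extra haplotypes;
  annotation against segmental-duplication intervals bounds, but does not
  eliminate, this concern.
* 4+-SNP blocks are reported but not given an exact parsimony treatment.
* No CRAM input; BAM only.
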