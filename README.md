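# localhap

Direct observation of local haplotypes — and of genomic heterogeneity — in
ordinary short-read sequencing data.

## The problem

SNP callers look at the genome one site at a time and assume a uniform
diploid genome: half the reads show `C`, half show `T`, so a `C/T`
heterozygous SNP is called. But the same pileup is equally consistent with a
*heterogeneous* tissue — a mixture of cell lineages, one homozygous `C` and
one homozygous `T`. Single sites cannot distinguish these. Combinations of
nearby sites can: a single read (or read pair) derives from exactly one DNA
molecule, hence exactly one haplotype. When two or more heterozygous SNPs
fall within a **block** — at most 500 bases, close enough for one fragment
to span — listing what each spanning fragment shows enumerates haplotypes
*directly*. A uniform diploid genome can show at most two haplotypes per
block; observing three or more is prima facie evidence that the sequenced
tissue is a mosaic of genetically distinct cell lineages.

`localhap` implements this analysis for anyone with a VCF of called SNPs and
the matching coordinate-sorted, indexed BAM: geneticists screening "normal"
genomes for somatic mosaicism, and cancer researchers quantifying tumor
heterogeneity around called variants.

## The method

For each sample:

1. **Heterozygous SNVs** are read from the VCF (indels and MNVs excluded).
2. **Blocks** are built greedily: runs of ≥ 2 het SNPs within 500 bases of
   the first SNP of the run.
3. **Allele patterns**: every fragment overlapping a block contributes the
   bases it shows at the block's SNP positions, with `_` at positions it
   misses. Filters: mapping quality ≥ 30 and base quality ≥ 30 (both
   Phred 30 ≈ 1/1000 error; a low-quality base means the read *skipped* that
   position), duplicates/secondary/supplementary alignments ignored, and
   patterns supported by fewer than 3 fragments discarded.
4. **Parsimonious clustering**: partial patterns that overlap without
   contradiction merge (`CG_` + `_GA` → `CGA`); completions are restricted
   to alleles actually observed at each position. The package reports the
   *exact* minimum number of complete haplotypes explaining the patterns
   (exhaustive minimum cover, the reference for 2–3-SNP blocks) alongside a
   deterministic greedy clustering for larger blocks.
5. **Classification**: ≤ 2 haplotypes → `homogeneous` (consistent with a
   uniform diploid genome); ≥ 3 → `heterogeneous`. Summary tables count
   blocks by observed haplotype number; BED annotation reports how many
   heterogeneous blocks escape, e.g., known segmental duplications; a
   windowed density track maps heterogeneity along the genome.

A built-in simulator (`truth_spec()` / `simulate_sample()`) plants a local
haplotype mixture, draws paired-end reads with configurable depth, insert,
qualities and substitution errors, and writes matched BAM + VCF + truth
files — so the whole pipeline is testable without external data.

## Worked example

The deterministic 2-SNP fixture encodes a block with SNPs 300 bases apart
(`A/G` and `G/T` heterozygous, four possible haplotypes):

```r
library(localhap)
fx <- figure1_fixture()
res <- lha_call(fx$vcf, fx$bam, fx$sample)
res[, c("pattern_counts", "n_observed_haplotypes", "classification")]
#>     pattern_counts n_observed_haplotypes classification
#> 1 GG:40;AG:13;AT:7                     3   heterogeneous
```

Three of the four possible haplotypes are directly observed — 40 fragments
show `G..G`, 13 show `A..G` and 7 show `A..T` — so the block cannot come
from a uniform diploid genome. Note that dismissing the 7 minority `A..T`
fragments as noise would also delete 7 of the 20 `A`-carrying reads that
supported calling the first SNP.

Partial patterns on a 3-SNP block are clustered exactly:

```r
minimum_haplotype_cover(c("CGG", "CG_", "_GA", "TTA"))
#> <lha_cluster> method=exact minimum_count=3
#> witness: CGA, CGG, TTA
```

A command-line front end with `call`, `simulate`, `summarize`, `cluster` and
`annotate` subcommands lives at `inst/cli/lha.R`.

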