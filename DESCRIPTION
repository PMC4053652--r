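Package: localhap
Title: Local Haplotype Analysis of Aligned Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Directly observes local haplotypes in next-generation sequencing
    data by enumerating the alleles each sequencing fragment (read or read
    pair) shows across blocks of two or three nearby heterozygous SNPs.
    Partial observations are combined by parsimonious clustering into the
    minimum set of complete haplotypes that explains the data, and blocks are
    classified as homogeneous (two or fewer haplotypes, consistent with a
    uniform diploid genome) or heterogeneous (three or more haplotypes,
    evidence of genomic mosaicism). Includes a deterministic read-mixture
    simulator that writes matched BAM and VCF fixtures from planted haplotype
    mixtures, frequency summaries of blocks by observed haplotype count,
    interval-overlap annotation against BED files, and per-window density
    tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
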