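#' Analyse one block: patterns, filtering, clustering, classification
#'
#' @param block An `lha_block`.
#' @param alignment_source BAM path or [Rsamtools::BamFile].
#' @param min_mapq,min_baseq,min_support Filter thresholds (defaults 30, 30,
#'   3).
#' @param exact_cap Largest block size for the exact parsimony solver.
#' @return One-row data frame in the block-table layout.
#' @export
analyze_block <- function(block, alignment_source, min_mapq = 30L,
                          min_baseq = 30L, min_support = 3L, exact_cap = 3L) {
  obs <- fetch_fragments(alignment_source, block, min_mapq = min_mapq,
                         min_baseq = min_baseq)
  pc <- apply_support_filter(patterns_from_fragments(block, obs),
                             min_support = min_support)
  n_obs <- observed_haplotype_count(pc, exact_cap = exact_cap)

  pats <- pc$counts$pattern
  if (length(pats) == 0L) {
    cl <- new_cluster_result(0L, character(0), "exact", list())
  } else if (block$n_snps <= exact_cap) {
    cl <- minimum_haplotype_cover(pats, max_snps = exact_cap)
  } else {
    cl <- greedy_cluster(pats, pc$counts$count)
  }

  fmt_counts <- function(values) {
    if (nrow(pc$counts) == 0L) return("")
    paste(sprintf("%s:%d", pc$counts$pattern, values), collapse = ";")
  }
  data.frame(
    sample = block$sample,
    chrom = block$chrom,
    block_start = min(block$pos) + 1L,
    block_end = max(block$pos) + 1L,
    n_snps = block$n_snps,
    snp_positions = paste(block$pos + 1L, collapse = ","),
    snp_alleles = paste(vapply(seq_len(block$n_snps), function(k) {
      paste(c(block$ref[k], block$alt[[k]]), collapse = "/")
    }, character(1)), collapse = ","),
    pattern_counts = fmt_counts(pc$counts$count),
    pattern_bridged_counts = fmt_counts(pc$counts$n_bridged),
    n_observed_haplotypes = n_obs,
    parsimony_min = cl$minimum_count,
    witness_haplotypes = paste(cl$witness, collapse = ","),
    classification = classify_block(n_obs),
    spanning_fragments = pc$spanning_fragments,
    total_fragments = pc$total_fragments,
    size_class = block$size_class,
    stringsAsFactors = FALSE)
}

#' Run the full local-haplotype analysis on a VCF + BAM pair
#'
#' End to end: heterozygous SNPs are read for the sample, partitioned into
#' blocks of 2+ SNPs within `max_span` bases, and each block's fragments are
#' reduced to quality-filtered allele patterns, support-filtered, clustered
#' parsimoniously and classified as homogeneous (<= 2 haplotypes) or
#' heterogeneous (>= 3).
#'
#' @param vcf_source VCF of called SNPs with a GT field for `sample`.
#' @param alignment_source Coordinate-sorted, indexed BAM of the same sample.
#' @param sample Sample identifier present in the VCF.
#' @param max_span Maximum block span in bases (default 500).
#' @param min_mapq,min_baseq,min_support Filter thresholds (defaults 30, 30,
#'   3).
#' @param rule Block-building rule, see [find_blocks()].
#' @param exact_cap Largest block size for the exact parsimony solver.
#' @param verbose Log per-stage counts with [message()].
#' @return Block-table data frame (one row per block, ordered by chromosome
#'   and start) with the columns documented in [write_block_table()].
#' @export
lha_call <- function(vcf_source, alignment_source, sample,
                     max_span = 500L, min_mapq = 30L, min_baseq = 30L,
                     min_support = 3L, rule = c("span", "gap"),
                     exact_cap = 3L, verbose = FALSE) {
  rule <- match.arg(rule)
  snps <- parse_het_snps(vcf_source, sample)
  if (verbose) message(nrow(snps), " heterozygous SNPs for sample ", sample)
  blocks <- unlist(lapply(split(snps, factor(snps$chrom,
                                             levels = unique(snps$chrom))),
                          find_blocks, max_span = max_span, rule = rule),
                   recursive = FALSE)
  if (verbose) {
    census <- size_census(blocks)
    message(length(blocks), " blocks (",
            paste(names(census), census, sep = ":", collapse = ", "), ")")
  }
  if (length(blocks) == 0L) return(empty_block_table())
  rows <- lapply(blocks, analyze_block, alignment_source = alignment_source,
                 min_mapq = min_mapq, min_baseq = min_baseq,
                 min_support = min_support, exact_cap = exact_cap)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$block_start), , drop = FALSE]
  rownames(out) <- NULL
  if (verbose) {
    message(sum(out$classification == "heterogeneous"),
            " heterogeneous block(s)")
  }
  out
}

#' @rdname lha_call
#' @param blocks List of `lha_block` objects (alternative entry point when
#'   SNPs/blocks were built by hand).
#' @export
block_results <- function(blocks, alignment_source, min_mapq = 30L,
                          min_baseq = 30L, min_support = 3L, exact_cap = 3L) {
  if (length(blocks) == 0L) return(empty_block_table())
  out <- do.call(rbind, lapply(blocks, analyze_block,
                               alignment_source = alignment_source,
                               min_mapq = min_mapq, min_baseq = min_baseq,
                               min_support = min_support,
                               exact_cap = exact_cap))
  out <- out[order(out$chrom, out$block_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
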