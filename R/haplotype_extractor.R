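#' Build allele-pattern counts for a block from fragment observations
#'
#' Each fragment yields exactly one allele pattern: the bases it shows at the
#' block's SNP positions, with `_` at skipped/uncovered positions. Fragments
#' covering fewer than two SNP positions carry no phase information and are
#' dropped from the pattern counts, but remain in `total_fragments` — this
#' keeps 0-haplotype blocks (well covered but never spanned) distinguishable
#' from blocks with no coverage at all.
#'
#' @param block An `lha_block`.
#' @param observations Fragment observation data frame from
#'   [fetch_fragments()] (already MAPQ/base-quality filtered).
#' @return An `lha_patterns` object: the block, a `counts` data frame
#'   (`pattern`, `count`, `n_bridged` — fragments whose pattern needed both
#'   mates), `spanning_fragments` (fragments covering >= 2 SNPs) and
#'   `total_fragments` (all fragments with >= 1 retained base).
#' @export
patterns_from_fragments <- function(block, observations) {
  n <- block$n_snps
  if (nrow(observations) > 0 &&
      (any(observations$snp_index < 1L) || any(observations$snp_index > n))) {
    stop("observation references a SNP index outside the block")
  }
  total <- length(unique(observations$fragment_id))
  counts <- data.frame(pattern = character(0), count = integer(0),
                       n_bridged = integer(0), stringsAsFactors = FALSE)
  spanning <- 0L
  if (total > 0L) {
    per_frag <- split(observations, observations$fragment_id)
    pats <- vapply(per_frag, function(g) {
      chars <- rep("_", n)
      chars[g$snp_index] <- g$base
      paste0(chars, collapse = "")
    }, character(1))
    covered <- vapply(per_frag, nrow, integer(1))
    bridged <- vapply(per_frag, function(g) g$bridged[1L], logical(1))
    span_sel <- covered >= 2L
    spanning <- sum(span_sel)
    if (spanning > 0L) {
      agg <- tapply(seq_along(pats)[span_sel], pats[span_sel], length)
      brg <- tapply(bridged[span_sel], pats[span_sel], sum)
      counts <- data.frame(pattern = names(agg),
                           count = as.integer(agg),
                           n_bridged = as.integer(brg[names(agg)]),
                           stringsAsFactors = FALSE)
      counts <- counts[order(-counts$count, counts$pattern), ]
      rownames(counts) <- NULL
    }
  }
  structure(list(block = block, counts = counts,
                 spanning_fragments = spanning, total_fragments = total),
            class = "lha_patterns")
}

#' @export
print.lha_patterns <- function(x, ...) {
  cat(sprintf("<lha_patterns> %s (%d SNPs): %d pattern(s), %d/%d spanning\n",
              x$block$chrom, x$block$n_snps, nrow(x$counts),
              x$spanning_fragments, x$total_fragments))
  if (nrow(x$counts)) print(x$counts)
  invisible(x)
}

#' Drop weakly supported allele patterns
#'
#' Read-based haplotype patterns supported by fewer than `min_support`
#' fragments are removed (default 3: a pattern must be seen at least three
#' times to be believed). The rule applies to literal patterns before
#' clustering, so a clustered haplotype may rest on several patterns of
#' three fragments each.
#'
#' @param pattern_counts An `lha_patterns` object.
#' @param min_support Minimum fragment support per pattern (default 3).
#' @return The filtered `lha_patterns` object.
#' @export
apply_support_filter <- function(pattern_counts, min_support = 3L) {
  pattern_counts$counts <-
    pattern_counts$counts[pattern_counts$counts$count >= min_support, ,
                          drop = FALSE]
  rownames(pattern_counts$counts) <- NULL
  pattern_counts
}

#' Observed haplotype count of a block
#'
#' For 2-SNP blocks, the number of distinct complete patterns (every
#' phase-informative pattern on a 2-SNP block is complete). For 3-SNP
#' blocks, the exact parsimony minimum — the smallest number of complete
#' haplotypes needed to explain the observed patterns. Blocks with 4+ SNPs
#' fall back to the greedy cluster count. Returns 0 when no qualifying
#' pattern exists.
#'
#' @param pattern_counts An `lha_patterns` object, support filter already
#'   applied.
#' @param exact_cap Largest block size handled by the exact solver
#'   (default 3).
#' @return Integer haplotype count.
#' @export
observed_haplotype_count <- function(pattern_counts, exact_cap = 3L) {
  pats <- pattern_counts$counts$pattern
  if (length(pats) == 0L) return(0L)
  n <- pattern_counts$block$n_snps
  if (n == 2L) {
    sum(!grepl("_", pats, fixed = TRUE))
  } else if (n <= exact_cap) {
    minimum_haplotype_cover(pats, max_snps = exact_cap)$minimum_count
  } else {
    greedy_cluster(pats, pattern_counts$counts$count)$minimum_count
  }
}
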