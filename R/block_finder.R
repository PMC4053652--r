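#' Partition heterozygous SNPs into blocks
#'
#' A block is a run of two or more heterozygous SNPs confined to a region
#' short enough that a single sequencing fragment can span it (500 bases by
#' default). SNPs are assigned greedily left to right: a block opens at the
#' first unassigned SNP and absorbs every subsequent SNP within `max_span`
#' bases of the block's *first* SNP (the anchor), guaranteeing that the
#' block's total footprint never exceeds a spanning fragment's reach. A SNP
#' exactly `max_span` bases from the anchor is included. Singleton runs are
#' discarded. The alternative rule — each SNP within `max_span` of its
#' predecessor — is selectable for sensitivity analysis via `rule = "gap"`.
#'
#' @param snps Data frame of heterozygous SNPs for one chromosome as returned
#'   by [parse_het_snps()]: columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `sample`, `genotype`, with strictly increasing positions.
#' @param max_span Maximum distance in bases from a block's first SNP to its
#'   last (default 500).
#' @param rule `"span"` (default; distance measured from the block's first
#'   SNP) or `"gap"` (distance from the previous SNP).
#' @return A list of `lha_block` objects. Blocks with 4 or more SNPs are
#'   returned too, flagged `size_class = "4plus"`; they are reported with
#'   pattern counts downstream but excluded from the exact parsimony solver
#'   by default.
#' @examples
#' snps <- data.frame(chrom = "chr1", pos = c(100L, 450L, 700L),
#'                    ref = "A", alt = "G", sample = "S", genotype = "0/1")
#' length(find_blocks(snps))  # 1: {100,450}; 700 is > 500 from 100 and alone
#' @export
find_blocks <- function(snps, max_span = 500L, rule = c("span", "gap")) {
  rule <- match.arg(rule)
  if (nrow(snps) == 0L) return(list())
  if (length(unique(snps$chrom)) != 1L) {
    stop("find_blocks() expects SNPs from a single chromosome")
  }
  if (anyDuplicated(snps$pos)) {
    stop("duplicate SNP positions on ", snps$chrom[1L])
  }
  if (is.unsorted(snps$pos, strictly = TRUE)) {
    stop("SNP positions must be strictly increasing")
  }

  pos <- snps$pos
  blocks <- list()
  i <- 1L
  n <- nrow(snps)
  while (i <= n) {
    j <- i
    while (j < n &&
           ((rule == "span" && pos[j + 1L] - pos[i] <= max_span) ||
            (rule == "gap" && pos[j + 1L] - pos[j] <= max_span))) {
      j <- j + 1L
    }
    if (j > i) blocks[[length(blocks) + 1L]] <- new_block(snps[i:j, ])
    i <- j + 1L
  }
  blocks
}

new_block <- function(snps) {
  n <- nrow(snps)
  structure(
    list(
      chrom = snps$chrom[1L],
      sample = snps$sample[1L],
      pos = snps$pos,                       # 0-based
      ref = snps$ref,
      alt = strsplit(snps$alt, ",", fixed = TRUE),
      n_snps = n,
      span = snps$pos[n] - snps$pos[1L],    # anchor-to-last distance
      size_class = if (n >= 4L) "4plus" else as.character(n)
    ),
    class = "lha_block"
  )
}

#' @export
print.lha_block <- function(x, ...) {
  cat(sprintf("<lha_block> %s:%s (%d SNPs, span %d)\n", x$chrom,
              paste(x$pos + 1L, collapse = ","), x$n_snps, x$span))
  invisible(x)
}

#' Count blocks by size class
#'
#' @param blocks List of `lha_block` objects.
#' @return Named integer vector with counts for classes `"2"`, `"3"` and
#'   `"4plus"`; the counts sum to `length(blocks)`.
#' @export
size_census <- function(blocks) {
  classes <- vapply(blocks, `[[`, character(1), "size_class")
  out <- c(`2` = 0L, `3` = 0L, `4plus` = 0L)
  tab <- table(classes)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Write block intervals as BED (0-based half-open)
#'
#' @param results Block-table data frame from [lha_call()] /
#'   [block_results()].
#' @param path Output path.
#' @export
write_blocks_bed <- function(results, path) {
  bed <- data.frame(
    chrom = results$chrom,
    start = results$block_start - 1L,
    end = results$block_end,
    name = results$classification
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
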