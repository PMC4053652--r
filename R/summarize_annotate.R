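#' Classify a block from its haplotype count
#'
#' Three or more observed haplotypes in a diploid sample cannot be explained
#' by a uniform genome: such blocks are `heterogeneous`. Two or fewer is
#' `homogeneous` — not inconsistent with a uniform diploid genome (0- and
#' 1-haplotype blocks reflect insufficient spanning coverage, not
#' homozygosity).
#'
#' @param n_haplotypes Integer haplotype count(s).
#' @return `"heterogeneous"` or `"homogeneous"` (vectorised).
#' @export
classify_block <- function(n_haplotypes) {
  ifelse(n_haplotypes >= 3L, "heterogeneous", "homogeneous")
}

#' Frequency table of blocks by observed haplotype count
#'
#' Tabulates, per sample, how many blocks of one size class show 0, 1, 2, ...
#' haplotypes, with percentages of the sample's total. Categories run from 0
#' to at least `2^k` for k called alleles per SNP (4 for 2-SNP blocks, 8 for
#' 3-SNP), extended if larger counts were observed (possible when reads show
#' bases outside the called allele set).
#'
#' @param results Block-table data frame.
#' @param size_class `"2"`, `"3"` or `"4plus"`; may be omitted when all rows
#'   already share one size class (mixed classes without an explicit choice
#'   are an error).
#' @param digits Decimal places for the percentage columns (0 for
#'   whole-genome style tables, 1 for exome style).
#' @return Data frame with one row per sample: `sample`, `size_class`,
#'   `total_blocks`, count columns `n_0 .. n_K` and percentage columns
#'   `pct_0 .. pct_K`. Counts always sum to `total_blocks`.
#' @export
haplotype_frequency_table <- function(results, size_class = NULL, digits = 0L) {
  if (is.null(size_class)) {
    sc <- unique(results$size_class)
    if (length(sc) > 1L) {
      stop("results mix size classes (", paste(sc, collapse = ", "),
           "); pass size_class explicitly")
    }
    size_class <- if (length(sc)) sc else "2"
  }
  res <- results[results$size_class == size_class, , drop = FALSE]
  k_max <- switch(size_class, `2` = 4L, `3` = 8L, 16L)
  if (nrow(res)) k_max <- max(k_max, res$n_observed_haplotypes)
  cats <- 0:k_max

  samples <- sort(unique(res$sample))
  rows <- lapply(samples, function(s) {
    n_obs <- res$n_observed_haplotypes[res$sample == s]
    cnt <- vapply(cats, function(k) sum(n_obs == k), integer(1))
    tot <- length(n_obs)
    pct <- round(100 * cnt / tot, digits)
    row <- data.frame(sample = s, size_class = size_class,
                      total_blocks = tot, stringsAsFactors = FALSE)
    row[paste0("n_", cats)] <- as.list(cnt)
    row[paste0("pct_", cats)] <- as.list(pct)
    row
  })
  if (length(rows) == 0L) {
    out <- data.frame(sample = character(0), size_class = character(0),
                      total_blocks = integer(0), stringsAsFactors = FALSE)
    out[paste0("n_", cats)] <- lapply(cats, function(.) integer(0))
    out[paste0("pct_", cats)] <- lapply(cats, function(.) numeric(0))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname haplotype_frequency_table
#' @param path Output path for the summary TSV.
#' @export
write_summary_table <- function(results, path, size_class = NULL, digits = 0L) {
  tab <- haplotype_frequency_table(results, size_class, digits)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

validate_bed <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2L]))) ||
        is.na(suppressWarnings(as.integer(f[3L])))) {
      stop("malformed BED line ", i, " in ", path, ": ", lines[i])
    }
  }
  invisible(path)
}

as_interval_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  validate_bed(x)
  rtracklayer::import(x, format = "BED")
}

#' Annotate blocks against named interval sets
#'
#' Labels each block with every interval set (gene features, segmental
#' duplications, ...) it overlaps by at least one base, using half-open
#' interval arithmetic. Also reports, per set, the fraction of heterogeneous
#' blocks that do *not* overlap it — the quantity used to argue that
#' heterogeneity is not explained by segmental duplication.
#'
#' @param results Block-table data frame.
#' @param interval_sets Named list of BED file paths or `GRanges` objects.
#' @return `results` with an `annotations` column (comma-joined set labels,
#'   `""` when none) and attribute `het_outside_fraction`: a named numeric
#'   vector with, for each set, the fraction of heterogeneous blocks not
#'   overlapping it (`NaN` when there are no heterogeneous blocks).
#' @export
annotate_blocks <- function(results, interval_sets) {
  stopifnot(is.list(interval_sets), !is.null(names(interval_sets)),
            all(nzchar(names(interval_sets))))
  blocks_gr <- GenomicRanges::GRanges(
    results$chrom,
    IRanges::IRanges(start = results$block_start, end = results$block_end))
  labels <- rep("", nrow(results))
  hit_mat <- matrix(FALSE, nrow(results), length(interval_sets),
                    dimnames = list(NULL, names(interval_sets)))
  for (nm in names(interval_sets)) {
    gr <- as_interval_granges(interval_sets[[nm]])
    hit_mat[, nm] <- IRanges::overlapsAny(blocks_gr, gr, ignore.strand = TRUE)
  }
  results$annotations <- apply(hit_mat, 1L, function(h) {
    paste(colnames(hit_mat)[h], collapse = ",")
  })
  het <- results$classification == "heterogeneous"
  outside <- vapply(names(interval_sets), function(nm) {
    mean(!hit_mat[het, nm])
  }, numeric(1))
  attr(results, "het_outside_fraction") <- outside
  results
}

#' Assign blocks to mutually exclusive feature categories by precedence
#'
#' When a block overlaps several gene-feature sets (say exon and intron), a
#' single category is assigned by the precedence order of `feature_sets`
#' (first match wins); blocks overlapping none get `fallback` (e.g.
#' "intergenic").
#'
#' @param results Block-table data frame.
#' @param feature_sets Named list of BED paths / `GRanges`, highest
#'   precedence first.
#' @param fallback Category for blocks overlapping no set.
#' @return `results` with a `feature_category` column.
#' @export
feature_category <- function(results, feature_sets, fallback = "intergenic") {
  ann <- annotate_blocks(results, feature_sets)
  hits <- strsplit(ann$annotations, ",", fixed = TRUE)
  ann$feature_category <- vapply(hits, function(h) {
    m <- intersect(names(feature_sets), h)
    if (length(m)) m[1L] else fallback
  }, character(1))
  attr(ann, "het_outside_fraction") <- NULL
  ann
}

#' Per-window block density track
#'
#' Counts homogeneous and heterogeneous blocks per fixed-size genomic window
#' (a block is assigned to the window containing its start). Window sums
#' equal the class totals.
#'
#' @param results Block-table data frame.
#' @param window Window size in bases (default 1e6).
#' @return Data frame with `chrom`, `window_start` (0-based),
#'   `window_end`, `classification`, `n_blocks`; empty when there are no
#'   blocks.
#' @export
density_track <- function(results, window = 1e6) {
  if (nrow(results) == 0L) {
    return(data.frame(chrom = character(0), window_start = numeric(0),
                      window_end = numeric(0), classification = character(0),
                      n_blocks = integer(0), stringsAsFactors = FALSE))
  }
  win <- floor((results$block_start - 1L) / window)
  key <- paste(results$chrom, win, results$classification, sep = "\r")
  agg <- tapply(seq_len(nrow(results)), key, length)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    window_start = as.numeric(vapply(parts, `[`, character(1), 2L)) * window,
    window_end = (as.numeric(vapply(parts, `[`, character(1), 2L)) + 1) * window,
    classification = vapply(parts, `[`, character(1), 3L),
    n_blocks = as.integer(agg),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$window_start, out$classification), ]
  rownames(out) <- NULL
  out
}

#' @rdname density_track
#' @param path Output path; one bedGraph-style file per classification is
#'   written with the classification appended to the name.
#' @export
write_density_track <- function(results, path, window = 1e6) {
  trk <- density_track(results, window)
  for (cls in c("homogeneous", "heterogeneous")) {
    sub <- trk[trk$classification == cls,
               c("chrom", "window_start", "window_end", "n_blocks")]
    utils::write.table(sub, sub("(\\.[^.]*)?$", paste0(".", cls, "\\1"), path),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(trk)
}
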