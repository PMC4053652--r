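# minimal block-table rows for summary/annotation tests
result_rows <- function(n_obs, chrom = "chr1", start = NULL, size_class = "2",
                        sample = "S1", span = 300L) {
  if (length(n_obs) == 0L) return(localhap:::empty_block_table())
  if (is.null(start)) start <- seq(1000L, by = 5000L, length.out = length(n_obs))
  data.frame(sample = sample, chrom = chrom, block_start = as.integer(start),
             block_end = as.integer(start + span), n_snps = 2L,
             snp_positions = "", snp_alleles = "", pattern_counts = "",
             pattern_bridged_counts = "",
             n_observed_haplotypes = as.integer(n_obs),
             parsimony_min = as.integer(n_obs), witness_haplotypes = "",
             classification = classify_block(n_obs),
             spanning_fragments = 10L, total_fragments = 10L,
             size_class = size_class, stringsAsFactors = FALSE)
}

test_that("classification is a pure threshold on the haplotype count", {
  expect_identical(classify_block(3L), "heterogeneous")
  expect_identical(classify_block(2L), "homogeneous")
  expect_identical(classify_block(0L), "homogeneous")
  expect_identical(classify_block(c(0, 1, 2, 3, 4)),
                   c("homogeneous", "homogeneous", "homogeneous",
                     "heterogeneous", "heterogeneous"))
})

test_that("frequency tables tabulate counts and percentages that conserve totals", {
  res <- result_rows(c(0L, 1L, 2L, 2L, 3L))
  tab <- haplotype_frequency_table(res)
  expect_identical(tab$total_blocks, 5L)
  expect_identical(unlist(tab[paste0("n_", 0:4)], use.names = FALSE),
                   c(1L, 1L, 2L, 1L, 0L))
  expect_identical(sum(unlist(tab[grep("^n_", names(tab))])),
                   tab$total_blocks)
  expect_identical(tab$pct_2, 40)

  one_dec <- haplotype_frequency_table(res, digits = 1L)
  expect_identical(one_dec$pct_0, 20.0)

  # the four spanning scenarios: one block each in categories 0,1,2,3
  scen <- result_rows(c(0L, 1L, 2L, 3L))
  stab <- haplotype_frequency_table(scen)
  expect_identical(unlist(stab[paste0("n_", 0:3)], use.names = FALSE),
                   rep(1L, 4L))

  mixed <- rbind(res, result_rows(2L, size_class = "3"))
  expect_error(haplotype_frequency_table(mixed), "mix size classes")
  expect_identical(haplotype_frequency_table(mixed, "3")$total_blocks, 1L)
})

test_that("interval annotation uses half-open one-base overlap", {
  res <- result_rows(c(3L, 3L), start = c(100L, 1000L), span = 299L)
  # block [100,400) in BED terms = 1-based [100,399]... block_end = 399
  sets <- list(
    touch = GenomicRanges::GRanges("chr1", IRanges::IRanges(399, 500)),
    miss  = GenomicRanges::GRanges("chr1", IRanges::IRanges(400, 500)))
  ann <- annotate_blocks(res, sets)
  expect_identical(ann$annotations, c("touch", ""))
  out <- attr(ann, "het_outside_fraction")
  expect_identical(out[["touch"]], 0.5)
  expect_identical(out[["miss"]], 1.0)
})

test_that("BED files drive annotation and malformed lines name the line", {
  res <- result_rows(c(3L, 3L, 2L), start = c(1000L, 11000L, 21000L))
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t900\t1100\tsegdup1", bed)
  ann <- annotate_blocks(res, list(segdup = bed))
  expect_identical(ann$annotations, c("segdup", "", ""))
  # 1 of 2 heterogeneous blocks overlaps: half are outside
  expect_identical(attr(ann, "het_outside_fraction")[["segdup"]], 0.5)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t900\t1100", "chr1\toops"), bad)
  expect_error(annotate_blocks(res, list(x = bad)), "line 2")
})

test_that("planted segmental-duplication overlap fraction is recovered", {
  # 10 heterogeneous blocks, exactly one inside the duplication interval
  res <- result_rows(rep(3L, 10L), start = seq(1000L, by = 10000L,
                                               length.out = 10L))
  segdup <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1400))
  ann <- annotate_blocks(res, list(segdup = segdup))
  expect_identical(attr(ann, "het_outside_fraction")[["segdup"]], 0.9)
})

test_that("annotation is independent of interval ordering", {
  res <- result_rows(c(3L, 2L), start = c(1000L, 50000L))
  iv <- data.frame(start = c(40000, 900), end = c(60000, 1500))
  g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(iv$start, iv$end))
  g2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rev(iv$start),
                                                        rev(iv$end)))
  expect_identical(annotate_blocks(res, list(s = g1))$annotations,
                   annotate_blocks(res, list(s = g2))$annotations)
})

test_that("feature categories are assigned by precedence", {
  res <- result_rows(c(2L, 2L, 2L), start = c(1000L, 11000L, 21000L))
  exon <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1100, 1200))
  intron <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1000, 11000),
                                                            c(2000, 12000)))
  fc <- feature_category(res, list(exonic = exon, intronic = intron))
  expect_identical(fc$feature_category, c("exonic", "intronic", "intergenic"))
})

test_that("density windows conserve class totals", {
  expect_identical(nrow(density_track(result_rows(integer(0)))), 0L)

  res <- result_rows(c(2L, 2L, 2L, 3L), start = c(1e4, 2e4, 3e4, 1.2e6))
  trk <- density_track(res)
  expect_identical(trk$n_blocks[trk$window_start == 0], 3L)
  expect_identical(sum(trk$n_blocks), nrow(res))
  for (cls in c("homogeneous", "heterogeneous")) {
    expect_identical(sum(trk$n_blocks[trk$classification == cls]),
                     sum(res$classification == cls))
  }
})
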