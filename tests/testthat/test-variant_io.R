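make_multi_sample_vcf <- function(path = tempfile(fileext = ".vcf")) {
  write_test_vcf(path, c(
    vcf_record("chr1", 101, "A", "G", c("0/1", "1/1")),   # het in S1 only
    vcf_record("chr1", 201, "C", "T", c("1/1", "0|1")),   # het in S2 only
    vcf_record("chr1", 301, "G", "GT", c("0/1", "0/1")),  # indel: excluded
    vcf_record("chr1", 401, "AT", "GC", c("0/1", "0/1")), # MNV: excluded
    vcf_record("chr1", 501, "A", "C,T", c("1/2", "0/0")), # multiallelic het
    vcf_record("chr1", 601, "T", "A", c("./.", "0/1")),   # missing GT in S1
    vcf_record("chr2", 51, "G", "A", c("0/1", "0/1"))
  ), samples = c("S1", "S2"), contigs = c(chr1 = 10000L, chr2 = 10000L))
}

test_that("only heterozygous SNVs are returned, 0-based, per sample", {
  vcf <- make_multi_sample_vcf()
  s1 <- parse_het_snps(vcf, "S1")
  expect_identical(s1$pos, c(100L, 500L, 50L))
  expect_identical(s1$chrom, c("chr1", "chr1", "chr2"))
  expect_identical(s1$alt[1], "G")
  expect_identical(s1$alt[2], "C,T")
  expect_identical(s1$genotype[2], "1/2")

  s2 <- parse_het_snps(vcf, "S2")
  expect_identical(s2$pos, c(200L, 600L, 50L))
  expect_false(identical(s1$pos, s2$pos))  # per-sample lists differ

  # re-reading is deterministic
  expect_identical(parse_het_snps(vcf, "S1"), s1)
})

test_that("unknown samples and unsorted VCFs are hard errors", {
  vcf <- make_multi_sample_vcf()
  expect_error(parse_het_snps(vcf, "NOPE"), "available: S1, S2")

  unsorted <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    vcf_record("chr1", 500, "A", "G", "0/1"),
    vcf_record("chr1", 100, "C", "T", "0/1")))
  expect_error(parse_het_snps(unsorted, "S1"), "not sorted")

  interleaved <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    vcf_record("chr1", 100, "A", "G", "0/1"),
    vcf_record("chr2", 100, "C", "T", "0/1"),
    vcf_record("chr1", 200, "C", "T", "0/1")),
    contigs = c(chr1 = 10000L, chr2 = 10000L))
  expect_error(parse_het_snps(interleaved, "S1"), "interleave")
})

test_that("malformed genotypes are skipped with a warning", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    vcf_record("chr1", 100, "A", "G", "0/1"),
    vcf_record("chr1", 200, "C", "T", "0/1/1")))
  expect_warning(out <- parse_het_snps(vcf, "S1"), "malformed GT")
  expect_identical(out$pos, 99L)   # POS 100 is 0-based 99
})

test_that("quality and flag filters gate fragment observations", {
  blk <- make_block(c(199L, 299L), ref = c("A", "G"), alt = c("G", "T"))
  q40 <- qual_of(40L, 50L)
  seqA <- strrep("A", 50)
  reads <- rbind(
    sam_pair("ok",   180, 280, seqA, seqA, q40, q40),
    sam_pair("lowmapq", 180, 280, seqA, seqA, q40, q40, mapq = 10L),
    sam_pair("dup",  180, 280, seqA, seqA, q40, q40,
             flag1 = 99L + 1024L, flag2 = 147L + 1024L),
    # base quality 20 at SNP 1 (ref pos 200 = offset 21 in read1)
    sam_pair("lowbq", 180, 280, seqA, seqA,
             paste0(qual_of(40L, 20L), intToUtf8(20L + 33L),
                    qual_of(40L, 29L)), q40))
  bam <- write_test_bam(reads)

  obs <- fetch_fragments(bam, blk)
  expect_false("lowmapq" %in% obs$fragment_id)
  expect_false("dup" %in% obs$fragment_id)
  expect_identical(sort(obs$snp_index[obs$fragment_id == "ok"]), c(1L, 2L))
  # low base quality at SNP 1 means that position was skipped
  expect_identical(obs$snp_index[obs$fragment_id == "lowbq"], 2L)

  # lowering thresholds never loses observations
  relaxed <- fetch_fragments(bam, blk, min_mapq = 0L, min_baseq = 0L)
  expect_gte(nrow(relaxed), nrow(obs))
  key <- function(d) paste(d$fragment_id, d$snp_index)
  expect_true(all(key(obs) %in% key(relaxed)))
})

test_that("mates are resolved to one observation per position", {
  # SNPs at ref pos 200 and 240; read1 [180,230) covers SNP 1, read2
  # [200,250) covers both, so the mates share SNP 1
  blk <- make_block(c(199L, 239L), ref = c("A", "G"), alt = c("G", "T"))
  q40 <- qual_of(40L, 50L)
  seqA <- strrep("A", 50)
  reads <- rbind(
    sam_pair("agree", 180, 200, seqA, seqA, q40, q40),
    # read2 shows C at SNP 1 (its first base), disagreeing with read1
    sam_pair("conflict", 180, 200, seqA,
             paste0("C", strrep("A", 49)), q40, q40))
  bam <- write_test_bam(reads)
  obs <- fetch_fragments(bam, blk)

  agree <- obs[obs$fragment_id == "agree", ]
  expect_identical(sort(agree$snp_index), c(1L, 2L))  # SNP 1 counted once
  expect_identical(anyDuplicated(paste(obs$fragment_id, obs$snp_index)), 0L)

  conflict <- obs[obs$fragment_id == "conflict", ]
  expect_identical(conflict$snp_index, 2L)    # disagreeing position skipped
})

test_that("deletions across a SNP are skips; absent chromosomes warn", {
  blk <- make_block(c(199L, 299L), ref = c("A", "G"), alt = c("G", "T"))
  q40 <- qual_of(40L, 50L)
  seqA <- strrep("A", 50)
  reads <- sam_pair("del", 190, 280, seqA, seqA, q40, q40,
                    cigar1 = "5M10D45M")  # deletion spans ref pos 195..204
  bam <- write_test_bam(reads)
  obs <- fetch_fragments(bam, blk)
  expect_identical(obs$snp_index[obs$fragment_id == "del"], 2L)
  expect_true(all(obs$bridged[obs$fragment_id == "del"] == FALSE))

  other <- make_block(c(199L, 299L), chrom = "chrZ")
  expect_warning(res <- fetch_fragments(bam, other), "absent")
  expect_identical(nrow(res), 0L)

  expect_error(fetch_fragments(tempfile(fileext = ".bam"), blk), "index")
})

test_that("pair-bridged fragments are flagged", {
  blk <- make_block(c(199L, 399L), ref = c("A", "G"), alt = c("G", "T"))
  q40 <- qual_of(40L, 50L)
  seqA <- strrep("A", 50)
  reads <- sam_pair("bridge", 180, 380, seqA, seqA, q40, q40)
  bam <- write_test_bam(reads)
  obs <- fetch_fragments(bam, blk)
  expect_identical(sort(obs$snp_index), c(1L, 2L))
  expect_true(all(obs$bridged))
})

test_that("block tables round-trip through TSV", {
  fx <- figure1_fixture()
  res <- lha_call(fx$vcf, fx$bam, fx$sample)
  path <- tempfile(fileext = ".tsv")
  write_block_table(res, path)
  expect_identical(read_block_table(path), res)

  empty_path <- tempfile(fileext = ".tsv")
  write_block_table(localhap:::empty_block_table(), empty_path)
  expect_identical(length(readLines(empty_path)), 1L)   # header only
  expect_identical(nrow(read_block_table(empty_path)), 0L)
})
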