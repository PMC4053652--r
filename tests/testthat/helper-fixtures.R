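# Shared helpers: tiny VCF/BAM builders and random pattern generators.

het_snp_df <- function(pos, chrom = "chr1", ref = "A", alt = "G",
                       sample = "S1") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             sample = sample, genotype = "0/1", stringsAsFactors = FALSE)
}

make_block <- function(pos, chrom = "chr1", ref = NULL, alt = NULL,
                       sample = "S1") {
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  snps <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                     alt = alt, sample = sample, genotype = "0/1",
                     stringsAsFactors = FALSE)
  localhap:::new_block(snps)
}

# long-format fragment observation rows, as fetch_fragments() returns
obs_df <- function(fragment_id, snp_index, base, baseq = 40L, mapq = 60L,
                   bridged = FALSE) {
  data.frame(fragment_id = fragment_id, snp_index = as.integer(snp_index),
             base = base, baseq = baseq, mapq = mapq, bridged = bridged,
             stringsAsFactors = FALSE)
}

# observations encoding given patterns with given multiplicities
obs_from_patterns <- function(counts) {
  rows <- list()
  frag <- 0L
  for (p in names(counts)) {
    chars <- strsplit(p, "")[[1L]]
    for (i in seq_len(counts[[p]])) {
      frag <- frag + 1L
      cov <- which(chars != "_")
      rows[[length(rows) + 1L]] <-
        obs_df(sprintf("f%05d", frag), cov, chars[cov])
    }
  }
  do.call(rbind, rows)
}

pattern_counts_fixture <- function(counts, n_snps = nchar(names(counts)[1L])) {
  block <- make_block(seq(100L, by = 150L, length.out = n_snps))
  patterns_from_fragments(block, obs_from_patterns(counts))
}

write_test_vcf <- function(path, records, samples = "S1",
                           contigs = c(chr1 = 10000L)) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, "100", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# paired alignment rows in the layout write_reads_bam() expects
sam_pair <- function(qname, pos1, pos2, seq1, seq2, qual1, qual2,
                     mapq = 60L, flag1 = 99L, flag2 = 147L,
                     cigar1 = NULL, cigar2 = NULL) {
  rl1 <- nchar(seq1); rl2 <- nchar(seq2)
  if (is.null(cigar1)) cigar1 <- paste0(rl1, "M")
  if (is.null(cigar2)) cigar2 <- paste0(rl2, "M")
  tlen <- pos2 + rl2 - pos1
  rbind(
    data.frame(qname = qname, flag = flag1, pos = pos1, mapq = mapq,
               cigar = cigar1, mpos = pos2, tlen = tlen, seq = seq1,
               qual = qual1, stringsAsFactors = FALSE),
    data.frame(qname = qname, flag = flag2, pos = pos2, mapq = mapq,
               cigar = cigar2, mpos = pos1, tlen = -tlen, seq = seq2,
               qual = qual2, stringsAsFactors = FALSE))
}

write_test_bam <- function(reads, chrom = "chr1", seqlen = 10000L,
                           dir = tempfile("bam_")) {
  dir.create(dir, showWarnings = FALSE)
  localhap:::write_reads_bam(reads, chrom, seqlen, file.path(dir, "t"))
}

qual_of <- function(q, n) strrep(intToUtf8(q + 33L), n)

# random partial patterns over per-position allele pools
random_pattern_set <- function(n_snps, n_patterns, gap_prob = 0.3,
                               n_alleles = 2L) {
  pools <- lapply(seq_len(n_snps), function(i) {
    sample(c("A", "C", "G", "T"), n_alleles)
  })
  pats <- replicate(n_patterns, {
    repeat {
      chars <- vapply(pools, sample, character(1), size = 1L)
      gap <- stats::runif(n_snps) < gap_prob
      if (!all(gap)) break
    }
    chars[gap] <- "_"
    paste0(chars, collapse = "")
  })
  unique(pats)
}
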