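#' Specification of a planted local-haplotype mixture
#'
#' Describes a short reference segment carrying a block of planted SNPs and a
#' mixture of local haplotypes with given proportions — the model of a
#' possibly heterogeneous (mosaic) diploid tissue in which each sequenced
#' fragment derives from exactly one haplotype. [simulate_sample()] draws
#' paired-end reads from the mixture and writes matched BAM + VCF + truth
#' files.
#'
#' @param snp_offsets 0-based positions of the planted SNPs within the
#'   segment, strictly increasing.
#' @param haplotypes Named numeric vector: names are allele strings over
#'   `A,C,G,T` of length `length(snp_offsets)`, values are mixture
#'   proportions summing to 1.
#' @param depth Mean per-base read depth; the number of fragments is
#'   `ceiling(depth * segment_length / (2 * read_length))`.
#' @param segment_length Length of the synthetic reference segment.
#' @param reference_segment Optional explicit segment sequence (a string);
#'   generated from `seed` when `NULL`. Bases at `snp_offsets` are set to the
#'   first haplotype's alleles, which therefore serve as the REF alleles.
#' @param read_length,insert_mean,insert_sd Paired-end geometry in bases.
#' @param error_rate Per-base substitution probability (uniform over the
#'   three alternative bases).
#' @param baseq Constant Phred base quality assigned to simulated bases.
#' @param low_baseq_frac,low_baseq Fraction of bases downgraded to
#'   `low_baseq`, giving a mixed quality model (0 = constant qualities).
#' @param mapq Constant mapping quality assigned to all reads.
#' @param seed Random seed; identical specs with identical seeds give
#'   byte-identical outputs.
#' @param chrom,sample Names used in the emitted files.
#' @return An `lha_truth_spec` list, validated.
#' @export
truth_spec <- function(snp_offsets, haplotypes, depth,
                       segment_length = 700L, reference_segment = NULL,
                       read_length = 100L, insert_mean = 300L,
                       insert_sd = 30L, error_rate = 0,
                       baseq = 40L, low_baseq_frac = 0, low_baseq = 10L,
                       mapq = 60L, seed = 1L,
                       chrom = "sim1", sample = "SIM") {
  spec <- structure(
    list(snp_offsets = as.integer(snp_offsets), haplotypes = haplotypes,
         depth = depth, segment_length = as.integer(segment_length),
         reference_segment = reference_segment,
         read_length = as.integer(read_length),
         insert_mean = insert_mean, insert_sd = insert_sd,
         error_rate = error_rate, baseq = as.integer(baseq),
         low_baseq_frac = low_baseq_frac, low_baseq = as.integer(low_baseq),
         mapq = as.integer(mapq), seed = as.integer(seed),
         chrom = chrom, sample = sample),
    class = "lha_truth_spec")
  validate_truth_spec(spec)
  spec
}

validate_truth_spec <- function(spec) {
  with(spec, {
    if (length(snp_offsets) < 1L || is.unsorted(snp_offsets, strictly = TRUE))
      stop("snp_offsets must be strictly increasing")
    if (min(snp_offsets) < 0L || max(snp_offsets) >= segment_length)
      stop("snp_offsets must lie within the segment")
    if (is.null(names(haplotypes)) || any(!nzchar(names(haplotypes))))
      stop("haplotypes must be a named numeric vector of proportions")
    if (any(nchar(names(haplotypes)) != length(snp_offsets)))
      stop("every haplotype allele string must have one base per SNP")
    if (!all(strsplit(paste(names(haplotypes), collapse = ""), "")[[1L]] %in%
             c("A", "C", "G", "T")))
      stop("haplotype alleles must be A/C/G/T")
    if (any(haplotypes <= 0) || abs(sum(haplotypes) - 1) > 1e-8)
      stop("haplotype proportions must be positive and sum to 1")
    if (depth < 0) stop("depth must be non-negative")
    if (read_length < 1L || read_length > segment_length)
      stop("read_length must be in [1, segment_length]")
    if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
    if (low_baseq_frac < 0 || low_baseq_frac > 1)
      stop("low_baseq_frac must be in [0,1]")
    if (!is.null(reference_segment) &&
        nchar(reference_segment) != segment_length)
      stop("reference_segment length disagrees with segment_length")
  })
  invisible(spec)
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

random_segment <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_bases <- function(seq_chars, idx, bases) {
  seq_chars[idx] <- bases
  seq_chars
}

# Draw fragments and build the alignment rows (one per read) plus truth info.
simulate_reads <- function(spec) {
  with_seed(spec$seed, {
    L <- spec$segment_length
    rl <- spec$read_length
    seg <- spec$reference_segment
    if (is.null(seg)) seg <- random_segment(L)
    seg_chars <- strsplit(seg, "")[[1L]]
    hap1 <- strsplit(names(spec$haplotypes)[1L], "")[[1L]]
    seg_chars <- substitute_bases(seg_chars, spec$snp_offsets + 1L, hap1)

    n_frag <- if (spec$depth == 0) 0L else
      as.integer(ceiling(spec$depth * L / (2 * rl)))
    reads <- NULL
    assigned <- character(0)
    if (n_frag > 0L) {
      assigned <- sample(names(spec$haplotypes), n_frag, replace = TRUE,
                         prob = spec$haplotypes)
      insert <- pmin(pmax(as.integer(round(
        stats::rnorm(n_frag, spec$insert_mean, spec$insert_sd))), rl), L)
      start <- vapply(insert, function(ins) {
        sample.int(L - ins + 1L, 1L) - 1L   # 0-based fragment start
      }, integer(1))

      make_read <- function(s0) {
        # s0: 0-based read start; returns the haplotype-bearing read sequence
        function(i) {
          chars <- seg_chars[(s0[i] + 1L):(s0[i] + rl)]
          inside <- which(spec$snp_offsets >= s0[i] &
                            spec$snp_offsets < s0[i] + rl)
          if (length(inside)) {
            hap <- strsplit(assigned[i], "")[[1L]]
            chars[spec$snp_offsets[inside] - s0[i] + 1L] <- hap[inside]
          }
          if (spec$error_rate > 0) {
            err <- which(stats::runif(rl) < spec$error_rate)
            for (e in err) {
              chars[e] <- sample(setdiff(c("A", "C", "G", "T"), chars[e]), 1L)
            }
          }
          paste0(chars, collapse = "")
        }
      }
      s1 <- start
      s2 <- start + insert - rl
      seq1 <- vapply(seq_len(n_frag), make_read(s1), character(1))
      seq2 <- vapply(seq_len(n_frag), make_read(s2), character(1))
      qual_string <- function() {
        q <- rep(spec$baseq, rl)
        if (spec$low_baseq_frac > 0) {
          low <- stats::runif(rl) < spec$low_baseq_frac
          q[low] <- spec$low_baseq
        }
        intToUtf8(q + 33L)
      }
      qual1 <- vapply(seq_len(n_frag), function(i) qual_string(), character(1))
      qual2 <- vapply(seq_len(n_frag), function(i) qual_string(), character(1))
      qname <- sprintf("frag%06d", seq_len(n_frag))
      reads <- rbind(
        data.frame(qname = qname, flag = 99L, pos = s1 + 1L,
                   mapq = spec$mapq, cigar = paste0(rl, "M"),
                   mpos = s2 + 1L, tlen = insert, seq = seq1, qual = qual1,
                   stringsAsFactors = FALSE),
        data.frame(qname = qname, flag = 147L, pos = s2 + 1L,
                   mapq = spec$mapq, cigar = paste0(rl, "M"),
                   mpos = s1 + 1L, tlen = -insert, seq = seq2, qual = qual2,
                   stringsAsFactors = FALSE))
    }

    # VCF records: REF is the segment base (= haplotype 1 allele); every
    # planted site is emitted as heterozygous, emulating caller output
    vcf_records <- lapply(seq_along(spec$snp_offsets), function(j) {
      alleles <- unique(substr(names(spec$haplotypes), j, j))
      ref <- seg_chars[spec$snp_offsets[j] + 1L]
      alts <- setdiff(alleles, ref)
      if (length(alts) == 0L) alts <- setdiff(c("A", "C", "G", "T"), ref)[1L]
      list(pos = spec$snp_offsets[j] + 1L, ref = ref,
           alt = paste(alts, collapse = ","), gt = "0/1")
    })

    list(reads = reads, segment = paste0(seg_chars, collapse = ""),
         vcf_records = vcf_records,
         truth = data.frame(haplotype = names(spec$haplotypes),
                            proportion = unname(spec$haplotypes),
                            n_fragments = as.integer(
                              table(factor(assigned,
                                           levels = names(spec$haplotypes)))),
                            stringsAsFactors = FALSE))
  })
}

write_reads_bam <- function(reads, chrom, seqlen, dest_prefix) {
  sam <- paste0(dest_prefix, ".sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, seqlen))
  body <- character(0)
  if (!is.null(reads) && nrow(reads) > 0L) {
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s",
                    reads$qname, reads$flag, chrom, reads$pos, reads$mapq,
                    reads$cigar, reads$mpos, reads$tlen, reads$seq, reads$qual)
  }
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, dest_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

write_sim_vcf <- function(vcf_records, chrom, seqlen, sample, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, seqlen),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- vapply(vcf_records, function(r) {
    sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\t.\tGT\t%s",
            chrom, r$pos, r$ref, r$alt, r$gt)
  }, character(1))
  writeLines(c(header, body), path)
  path
}

#' Simulate a sequenced sample from a planted haplotype mixture
#'
#' Draws paired-end fragments from the mixture (each fragment from exactly
#' one haplotype, placed uniformly along the segment), applies the
#' substitution-error and quality models, and writes a coordinate-sorted,
#' indexed BAM, a matched VCF with heterozygous records at the planted SNP
#' positions, and a plain-text truth table. Outputs are deterministic for a
#' fixed spec and seed.
#'
#' @param spec An `lha_truth_spec` from [truth_spec()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return List with paths `bam`, `vcf`, `truth`, the truth data frame, and
#'   the reference `segment` string.
#' @export
simulate_sample <- function(spec, dir = tempfile("lha_sim_"), prefix = "sim") {
  validate_truth_spec(spec)
  sim <- simulate_reads(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bam <- write_reads_bam(sim$reads, spec$chrom, spec$segment_length,
                         file.path(dir, prefix))
  vcf <- write_sim_vcf(sim$vcf_records, spec$chrom, spec$segment_length,
                       spec$sample, file.path(dir, paste0(prefix, ".vcf")))
  truth_path <- file.path(dir, paste0(prefix, ".truth.tsv"))
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(bam = bam, vcf = vcf, truth = sim$truth, truth_path = truth_path,
       segment = sim$segment, spec = spec)
}

# Deterministic reference segment for the worked-example fixtures.
fixture_segment <- function(n, snp_offsets, ref_alleles) {
  chars <- rep(c("A", "C", "G", "T"), length.out = n)
  substitute_bases(chars, snp_offsets + 1L, ref_alleles)
}

fixture_files <- function(dir, prefix, chrom, seqlen, sample,
                          reads, vcf_records) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bam <- write_reads_bam(reads, chrom, seqlen, file.path(dir, prefix))
  vcf <- write_sim_vcf(vcf_records, chrom, seqlen, sample,
                       file.path(dir, paste0(prefix, ".vcf")))
  list(bam = bam, vcf = vcf, sample = sample, chrom = chrom)
}

paired_fragment_reads <- function(qname, pattern_by_frag, starts1, starts2,
                                  rl, seg_chars, snp_offsets, baseq) {
  n <- length(qname)
  qual <- intToUtf8(rep(baseq + 33L, rl))
  read_seq <- function(s0, pat) {
    chars <- seg_chars[(s0 + 1L):(s0 + rl)]
    inside <- which(snp_offsets >= s0 & snp_offsets < s0 + rl)
    if (length(inside)) {
      hap <- strsplit(pat, "")[[1L]]
      rep_idx <- inside[hap[inside] != "_"]
      chars[snp_offsets[rep_idx] - s0 + 1L] <- hap[rep_idx]
    }
    paste0(chars, collapse = "")
  }
  insert <- starts2 + rl - starts1
  rbind(
    data.frame(qname = qname, flag = 99L, pos = starts1 + 1L, mapq = 60L,
               cigar = paste0(rl, "M"), mpos = starts2 + 1L, tlen = insert,
               seq = vapply(seq_len(n), function(i)
                 read_seq(starts1[i], pattern_by_frag[i]), character(1)),
               qual = qual, stringsAsFactors = FALSE),
    data.frame(qname = qname, flag = 147L, pos = starts2 + 1L, mapq = 60L,
               cigar = paste0(rl, "M"), mpos = starts1 + 1L, tlen = -insert,
               seq = vapply(seq_len(n), function(i)
                 read_seq(starts2[i], pattern_by_frag[i]), character(1)),
               qual = qual, stringsAsFactors = FALSE))
}

#' Worked-example fixture: a 2-SNP block with three observed haplotypes
#'
#' Encodes a 2-SNP block (SNPs 300 bases apart; A/G and G/T heterozygous)
#' with exactly 40 fragments showing G at both positions, 13 showing A..G and
#' 7 showing A..T — three of the four possible haplotypes, so the block is
#' heterogeneous. All qualities pass the default filters; fragments are
#' pair-bridged 100 bp reads. Fully deterministic.
#'
#' @param dir Output directory.
#' @return List with paths `bam`, `vcf`, plus `sample` and `chrom`.
#' @export
figure1_fixture <- function(dir = tempfile("lha_fig1_")) {
  seqlen <- 700L
  offsets <- c(200L, 500L)
  seg <- fixture_segment(seqlen, offsets, c("A", "G"))
  pats <- c(rep("AG", 13L), rep("AT", 7L), rep("GG", 40L))
  n <- length(pats)
  reads <- paired_fragment_reads(
    qname = sprintf("frag%04d", seq_len(n)), pattern_by_frag = pats,
    starts1 = rep(150L, n), starts2 = rep(450L, n), rl = 100L,
    seg_chars = seg, snp_offsets = offsets, baseq = 40L)
  vcf_records <- list(
    list(pos = 201L, ref = "A", alt = "G", gt = "0/1"),
    list(pos = 501L, ref = "G", alt = "T", gt = "0/1"))
  fixture_files(dir, "fig1", "chrB1", seqlen, "SIM", reads, vcf_records)
}

#' Worked-example fixture: a 3-SNP block with partial patterns
#'
#' Encodes a 3-SNP block whose filtered patterns are `CGG` (5), `CG_` (4),
#' `_GA` (4) and `TTA` (5): the partial patterns `CG_` and `_GA` merge into
#' `CGA` under parsimonious clustering, so the minimum explanation is the
#' three haplotypes `CGG`, `CGA`, `TTA`. Gaps arise from fragment geometry
#' (the pair does not cover the missing SNP). Fully deterministic.
#'
#' @inheritParams figure1_fixture
#' @export
figure2_fixture <- function(dir = tempfile("lha_fig2_")) {
  seqlen <- 700L
  offsets <- c(100L, 300L, 500L)
  seg <- fixture_segment(seqlen, offsets, c("C", "G", "G"))
  frags <- list(
    # full-span pairs: read1 covers SNPs 1-2, read2 covers SNP 3
    list(pat = "CGG", n = 5L, s1 = 60L, s2 = 350L),
    list(pat = "TTA", n = 5L, s1 = 60L, s2 = 350L),
    # read1 covers SNPs 1-2, read2 re-covers SNP 2 only -> gap at SNP 3
    list(pat = "CG_", n = 4L, s1 = 60L, s2 = 250L),
    # read1 covers SNP 2, read2 covers SNP 3 -> gap at SNP 1
    list(pat = "_GA", n = 4L, s1 = 250L, s2 = 450L))
  pats <- unlist(lapply(frags, function(f) rep(f$pat, f$n)))
  s1 <- unlist(lapply(frags, function(f) rep(f$s1, f$n)))
  s2 <- unlist(lapply(frags, function(f) rep(f$s2, f$n)))
  reads <- paired_fragment_reads(
    qname = sprintf("frag%04d", seq_along(pats)), pattern_by_frag = pats,
    starts1 = s1, starts2 = s2, rl = 250L,
    seg_chars = seg, snp_offsets = offsets, baseq = 40L)
  vcf_records <- list(
    list(pos = 101L, ref = "C", alt = "T", gt = "0/1"),
    list(pos = 301L, ref = "G", alt = "T", gt = "0/1"),
    list(pos = 501L, ref = "G", alt = "A", gt = "0/1"))
  fixture_files(dir, "fig2", "chrB2", seqlen, "SIM", reads, vcf_records)
}
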