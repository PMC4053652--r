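#' Read heterozygous SNPs for one sample from a VCF
#'
#' Scans a VCF (plain or bgzipped) and returns the single-nucleotide variant
#' records at which the named sample's genotype is heterozygous. Indel and
#' multi-nucleotide records are never admitted: the reference allele and
#' every alternate allele must be a single base in `A,C,G,T`. Positions are
#' converted to 0-based internally (outputs report 1-based coordinates).
#'
#' @param vcf_source Path to a VCF file (v4.x, plain or bgzipped).
#' @param sample Sample identifier; must match a sample column in the VCF.
#' @return Data frame with columns `chrom`, `pos` (0-based integer), `ref`,
#'   `alt` (comma-joined alternate alleles), `sample`, `genotype`, sorted by
#'   chromosome block and position as in the input.
#' @details Records with a malformed GT for the sample are skipped with a
#'   warning; an unknown sample name or an unsorted VCF is a hard error.
#' @export
parse_het_snps <- function(vcf_source, sample) {
  hdr <- VariantAnnotation::scanVcfHeader(vcf_source)
  avail <- VariantAnnotation::samples(hdr)
  if (!sample %in% avail) {
    stop("sample '", sample, "' not in VCF; available: ",
         paste(avail, collapse = ", "))
  }
  vcf <- VariantAnnotation::readVcf(vcf_source, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)

  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos1 <- GenomicRanges::start(rr)
  # sortedness: chromosomes in contiguous runs, positions non-decreasing within
  runs <- rle(chrom)$values
  if (anyDuplicated(runs)) stop("VCF is not sorted: chromosome records interleave")
  if (any(unlist(tapply(pos1, factor(chrom, levels = runs), is.unsorted)))) {
    stop("VCF is not sorted by position")
  }

  ref <- as.character(rr$REF)
  alt <- methods::as(VariantAnnotation::alt(vcf), "CharacterList")
  alt_chr <- S4Vectors::unstrsplit(alt, sep = ",")
  is_snv <- nchar(ref) == 1L & ref %in% c("A", "C", "G", "T") &
    vapply(alt, function(a) {
      length(a) >= 1L && all(nchar(a) == 1L) && all(a %in% c("A", "C", "G", "T"))
    }, logical(1))

  gt <- VariantAnnotation::geno(vcf)$GT[, sample]
  alleles <- strsplit(gt, "[/|]")
  valid_gt <- vapply(alleles, function(a) {
    length(a) == 2L && all(grepl("^[0-9]+$", a) | a == ".")
  }, logical(1))
  if (any(!valid_gt & is_snv)) {
    warning(sum(!valid_gt & is_snv), " SNV record(s) with malformed GT '",
            paste(unique(gt[!valid_gt & is_snv]), collapse = "','"),
            "' skipped for sample ", sample)
  }
  is_het <- valid_gt & vapply(alleles, function(a) {
    length(a) == 2L && !any(a == ".") && a[1L] != a[2L]
  }, logical(1))

  keep <- which(is_snv & is_het)
  data.frame(
    chrom = chrom[keep],
    pos = pos1[keep] - 1L,
    ref = ref[keep],
    alt = alt_chr[keep],
    sample = rep(sample, length(keep)),
    genotype = unname(gt[keep]),
    stringsAsFactors = FALSE
  )
}

phred_from_qual <- function(qual_strings) {
  lapply(qual_strings, function(q) utf8ToInt(q) - 33L)
}

#' Phred score to error probability
#'
#' @param q Phred-scaled quality score(s).
#' @return `10^(-q/10)`; quality 30 corresponds to a 1/1000 error
#'   probability, the threshold used for both base and mapping quality.
#' @export
phred_error_prob <- function(q) 10^(-q / 10)

#' Extract per-fragment allele observations at a block's SNP positions
#'
#' For every read pair (fragment) overlapping a block, records the base and
#' base quality observed at each SNP position, applying the quality filter
#' cascade: reads with mapping quality below `min_mapq` contribute nothing;
#' a base with quality below `min_baseq` at a SNP position means the read
#' skipped that position; duplicate-flagged, secondary, supplementary and
#' unmapped alignments contribute nothing; a deletion or soft-clip across a
#' SNP position is a skip. Mates of a pair are resolved to one observation
#' per position: agreeing mates count once (highest quality kept); mates
#' that disagree at a position make the fragment skip that position.
#'
#' @param alignment_source Path to a coordinate-sorted BAM with a `.bai`
#'   index, or a [Rsamtools::BamFile].
#' @param block An `lha_block` from [find_blocks()].
#' @param min_mapq,min_baseq Phred thresholds, both 30 by default
#'   (error probability 1/1000).
#' @param drop_noncalled Drop bases outside the called REF/ALT set at a SNP
#'   position (default `FALSE`: such bases are retained, since rare extra
#'   alleles are part of what the method can reveal).
#' @return Data frame with one row per retained (fragment, SNP) observation:
#'   `fragment_id`, `snp_index` (1-based index within the block), `base`,
#'   `baseq`, `mapq` (minimum over the fragment's contributing reads) and
#'   `bridged` (`TRUE` when no single read of the pair covers all of the
#'   fragment's retained positions, i.e. the pattern is pair-bridged).
#' @export
fetch_fragments <- function(alignment_source, block, min_mapq = 30L,
                            min_baseq = 30L, drop_noncalled = FALSE) {
  bf <- if (methods::is(alignment_source, "BamFile")) alignment_source
        else {
          idx <- paste0(alignment_source, ".bai")
          if (!file.exists(idx) &&
              !file.exists(sub("\\.bam$", ".bai", alignment_source))) {
            stop("BAM index not found for ", alignment_source)
          }
          Rsamtools::BamFile(alignment_source)
        }
  empty <- data.frame(fragment_id = character(0), snp_index = integer(0),
                      base = character(0), baseq = integer(0),
                      mapq = integer(0), bridged = logical(0))
  hdr_seqs <- names(Rsamtools::scanBamHeader(bf)[["targets"]])
  if (!block$chrom %in% hdr_seqs) {
    warning("chromosome ", block$chrom, " absent from alignment header")
    return(empty)
  }

  which <- GenomicRanges::GRanges(
    block$chrom,
    IRanges::IRanges(min(block$pos) + 1L, max(block$pos) + 1L))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"),
    which = which)
  res <- Rsamtools::scanBam(bf, param = param)[[1L]]
  if (length(res$qname) == 0L) return(empty)

  keep <- !is.na(res$mapq) & res$mapq >= min_mapq
  if (!any(keep)) return(empty)
  qname <- res$qname[keep]
  flag <- res$flag[keep]
  rpos <- res$pos[keep]
  mapq <- res$mapq[keep]
  cigar <- res$cigar[keep]
  seq_laid <- GenomicAlignments::sequenceLayer(res$seq[keep], cigar)
  qual_laid <- GenomicAlignments::sequenceLayer(
    methods::as(res$qual[keep], "BStringSet"), cigar)
  widths <- BiocGenerics::width(seq_laid)
  seq_chr <- as.character(seq_laid)
  qual_chr <- as.character(qual_laid)

  # distinguish the two reads of a pair: 0x40 first-in-pair, 0x80 second
  read_id <- paste0(qname, "/", bitwAnd(flag, 0xC0L))

  rows <- list()
  for (k in seq_along(block$pos)) {
    off <- (block$pos[k] + 1L) - rpos + 1L
    hit <- which(off >= 1L & off <= widths)
    if (length(hit) == 0L) next
    base <- substring(seq_chr[hit], off[hit], off[hit])
    bq <- utf8ToInt(paste0(substring(qual_chr[hit], off[hit], off[hit]),
                           collapse = "")) - 33L
    ok <- base %in% c("A", "C", "G", "T") & bq >= min_baseq
    if (drop_noncalled) {
      called <- c(block$ref[k], block$alt[[k]])
      ok <- ok & base %in% called
    }
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      fragment_id = qname[hit][ok], read_id = read_id[hit][ok],
      snp_index = k, base = base[ok], baseq = bq[ok],
      mapq = mapq[hit][ok], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  obs <- do.call(rbind, rows)

  # mate resolution: one observation per (fragment, position); disagreeing
  # mates mean the fragment skips that position
  key <- paste(obs$fragment_id, obs$snp_index, sep = "\r")
  resolved <- lapply(split(obs, key), function(g) {
    if (nrow(g) == 1L) return(g)
    if (length(unique(g$base)) > 1L) return(NULL)   # conflict -> skip
    g[which.max(g$baseq), , drop = FALSE]
  })
  obs <- do.call(rbind, resolved[!vapply(resolved, is.null, logical(1))])
  if (is.null(obs) || nrow(obs) == 0L) return(empty)
  rownames(obs) <- NULL

  # fragment-level mapq (min over contributing reads) and pair-bridging flag
  per_frag <- split(obs, obs$fragment_id)
  frag_mapq <- vapply(per_frag, function(g) min(g$mapq), integer(1))
  frag_bridged <- vapply(per_frag, function(g) {
    cov <- unique(g$snp_index)
    !any(vapply(split(g$snp_index, g$read_id),
                function(s) all(cov %in% s), logical(1)))
  }, logical(1))
  obs$mapq <- frag_mapq[obs$fragment_id]
  obs$bridged <- frag_bridged[obs$fragment_id]
  obs$read_id <- NULL
  obs <- obs[order(obs$fragment_id, obs$snp_index), ]
  rownames(obs) <- NULL
  obs
}

block_table_columns <- c(
  "sample", "chrom", "block_start", "block_end", "n_snps", "snp_positions",
  "snp_alleles", "pattern_counts", "pattern_bridged_counts",
  "n_observed_haplotypes", "parsimony_min", "witness_haplotypes",
  "classification", "spanning_fragments", "total_fragments", "size_class")

empty_block_table <- function() {
  cols <- stats::setNames(
    list(character(0), character(0), integer(0), integer(0), integer(0),
         character(0), character(0), character(0), character(0),
         integer(0), integer(0), character(0), character(0),
         integer(0), integer(0), character(0)),
    block_table_columns)
  do.call(data.frame, c(cols, stringsAsFactors = FALSE))
}

#' Write the per-block results table as TSV
#'
#' One row per block, ordered by chromosome then start; an empty result set
#' writes a header-only file. [read_block_table()] restores the exact data
#' frame.
#'
#' @param results Block-table data frame ([lha_call()] / [block_results()]).
#' @param path Output path.
#' @export
write_block_table <- function(results, path) {
  results <- results[order(results$chrom, results$block_start), , drop = FALSE]
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_block_table
#' @export
read_block_table <- function(path) {
  classes <- c(sample = "character", chrom = "character",
               block_start = "integer", block_end = "integer",
               n_snps = "integer", snp_positions = "character",
               snp_alleles = "character", pattern_counts = "character",
               pattern_bridged_counts = "character",
               n_observed_haplotypes = "integer", parsimony_min = "integer",
               witness_haplotypes = "character", classification = "character",
               spanning_fragments = "integer", total_fragments = "integer",
               size_class = "character")
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = unname(classes), na.strings = "NA",
                           stringsAsFactors = FALSE)
  for (col in c("snp_positions", "snp_alleles", "pattern_counts",
                "pattern_bridged_counts", "witness_haplotypes")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  out
}
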