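#' Parsimonious clustering of partial allele patterns
#'
#' A block's fragments yield allele patterns that may be partial: a fragment
#' that misses (or fails quality at) a SNP position shows a gap (`_`) there.
#' Parsimonious clustering asks for the minimum set of complete haplotypes
#' that explains every observed pattern, merging overlapping patterns that do
#' not contradict each other. Two routes are provided: a deterministic greedy
#' single-pass agglomeration, and an exact exhaustive minimum-cover solver
#' used as the reference for 2- and 3-SNP blocks.
#'
#' @name parsimony
NULL

pattern_chars <- function(p) strsplit(p, "", fixed = TRUE)[[1L]]

#' Test whether two allele patterns are compatible
#'
#' Patterns are compatible when they share at least one covered (non-gap)
#' position and agree at every position both cover. Patterns with disjoint
#' coverage are *not* compatible: they carry no mutual phase evidence, so
#' e.g. `A_` and `_G` must not be fused on overlap grounds alone.
#'
#' @param p1,p2 Allele patterns: strings over `A,C,G,T,_` of equal length,
#'   `_` marking an uncovered position.
#' @return `TRUE` or `FALSE`.
#' @examples
#' pattern_compatible("CG_", "_GA")  # TRUE: shared middle position agrees
#' pattern_compatible("CG_", "TTA")  # FALSE: disagreement
#' pattern_compatible("A_", "_G")    # FALSE: no shared covered position
#' @export
pattern_compatible <- function(p1, p2) {
  if (nchar(p1) != nchar(p2)) {
    stop("patterns have different lengths: ", p1, " vs ", p2)
  }
  c1 <- pattern_chars(p1)
  c2 <- pattern_chars(p2)
  shared <- c1 != "_" & c2 != "_"
  any(shared) && all(c1[shared] == c2[shared])
}

#' Merge two compatible allele patterns
#'
#' Position-wise union of two compatible patterns; a gap remains only where
#' both inputs are gapped. Merging is idempotent and absorbs sub-patterns.
#'
#' @inheritParams pattern_compatible
#' @return The merged pattern string.
#' @examples
#' pattern_merge("CG_", "_GA")  # "CGA"
#' @export
pattern_merge <- function(p1, p2) {
  if (!pattern_compatible(p1, p2)) {
    stop("cannot merge incompatible patterns: ", p1, " vs ", p2)
  }
  c1 <- pattern_chars(p1)
  c2 <- pattern_chars(p2)
  paste0(ifelse(c1 != "_", c1, c2), collapse = "")
}

new_cluster_result <- function(minimum_count, witness, method, merged_from) {
  structure(
    list(minimum_count = minimum_count, witness = witness,
         method = method, merged_from = merged_from),
    class = "lha_cluster"
  )
}

#' @export
print.lha_cluster <- function(x, ...) {
  cat(sprintf("<lha_cluster> method=%s minimum_count=%d\n",
              x$method, x$minimum_count))
  if (length(x$witness)) {
    cat("witness:", paste(x$witness, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Greedy single-pass clustering of allele patterns
#'
#' Deterministic agglomeration: patterns are processed in descending support
#' order (ties broken by ascending pattern string) and each is merged into
#' the first compatible existing cluster, else opens a new one. Greedy
#' clustering can over-count relative to the exact minimum on adversarial
#' gap structures; [minimum_haplotype_cover()] is the reference for 2- and
#' 3-SNP blocks, while greedy is the fallback reported for larger blocks.
#'
#' @param patterns Character vector of allele patterns (equal lengths).
#' @param counts Optional integer support per pattern (defaults to 1 each).
#' @return An `lha_cluster` with the cluster count, the cluster patterns
#'   (possibly still gapped) as `witness`, and a `merged_from` map from each
#'   cluster pattern to the input patterns it absorbed.
#' @examples
#' greedy_cluster(c("CGG", "CG_", "_GA", "TTA"))$minimum_count  # 3
#' @export
greedy_cluster <- function(patterns, counts = NULL) {
  if (length(patterns) == 0L) {
    return(new_cluster_result(0L, character(0), "greedy", list()))
  }
  if (is.null(counts)) counts <- rep(1L, length(patterns))
  stopifnot(length(counts) == length(patterns))
  ord <- order(-counts, patterns)
  patterns <- patterns[ord]

  clusters <- character(0)
  members <- list()
  for (p in patterns) {
    placed <- FALSE
    for (i in seq_along(clusters)) {
      if (pattern_compatible(clusters[i], p)) {
        clusters[i] <- pattern_merge(clusters[i], p)
        members[[i]] <- c(members[[i]], p)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters <- c(clusters, p)
      members <- c(members, list(p))
    }
  }
  names(members) <- clusters
  new_cluster_result(length(clusters), sort(clusters), "greedy", members)
}

candidate_haplotypes <- function(patterns) {
  len <- nchar(patterns[1L])
  per_pos <- lapply(seq_len(len), function(i) {
    a <- sort(unique(substr(patterns, i, i)))
    a <- setdiff(a, "_")
    if (length(a) == 0L) a <- "_"
    a
  })
  sort(apply(expand.grid(per_pos, stringsAsFactors = FALSE),
             1L, paste0, collapse = ""))
}

consistent_with <- function(pattern, candidates) {
  pc <- pattern_chars(pattern)
  cov <- which(pc != "_")
  vapply(candidates, function(h) {
    hc <- pattern_chars(h)
    all(hc[cov] == pc[cov])
  }, logical(1), USE.NAMES = FALSE)
}

#' Exact minimum haplotype cover of partial allele patterns
#'
#' Finds the smallest set of complete haplotypes such that every observed
#' pattern is consistent with at least one of them. Candidate alleles at each
#' position are restricted to alleles actually observed there — a completion
#' never introduces a base that no read showed (so `CG_` may complete to
#' `CGA` or `CGG` if those third bases were seen, never to an unseen `CGT`).
#' The search enumerates candidate subsets in increasing size, so the result
#' is a true minimum; among minima the lexicographically smallest witness set
#' is returned.
#'
#' @param patterns Character vector of allele patterns (equal lengths).
#' @param max_snps Refuse blocks longer than this (default 3): the candidate
#'   space grows as the product of per-position allele counts, and larger
#'   blocks should use [greedy_cluster()].
#' @return An `lha_cluster` with `method = "exact"`.
#' @examples
#' minimum_haplotype_cover(c("CGG", "CG_", "_GA", "TTA"))
#' minimum_haplotype_cover(c("A_", "_G"))$minimum_count  # 1: AG covers both
#' @export
minimum_haplotype_cover <- function(patterns, max_snps = 3L) {
  patterns <- unique(patterns)
  if (length(patterns) == 0L) {
    return(new_cluster_result(0L, character(0), "exact", list()))
  }
  len <- nchar(patterns[1L])
  if (any(nchar(patterns) != len)) stop("patterns have unequal lengths")
  if (len > max_snps) {
    stop("block has ", len, " SNPs; exact cover is capped at ", max_snps,
         " — use greedy_cluster() for larger blocks")
  }

  cands <- candidate_haplotypes(patterns)
  # cons[i, j]: pattern i is consistent with candidate j
  cons <- matrix(FALSE, length(patterns), length(cands))
  for (i in seq_along(patterns)) cons[i, ] <- consistent_with(patterns[i], cands)

  for (k in seq_along(cands)) {
    combos <- utils::combn(seq_along(cands), k)
    for (ci in seq_len(ncol(combos))) {
      sel <- combos[, ci]
      if (all(rowSums(cons[, sel, drop = FALSE]) > 0L)) {
        witness <- cands[sel]
        merged_from <- lapply(seq_along(sel), function(w) {
          # assign each pattern to the first witness consistent with it
          pats <- patterns[cons[, sel[w]] &
                             rowSums(cons[, sel[seq_len(w - 1L)],
                                          drop = FALSE]) == 0L]
          pats
        })
        names(merged_from) <- witness
        return(new_cluster_result(k, witness, "exact", merged_from))
      }
    }
  }
  stop("internal error: no cover found")  # unreachable: each pattern has a completion
}
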