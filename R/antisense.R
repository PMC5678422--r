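#' Global antisense proportion across genes
#'
#' The null "expected success rate" of the trap statistic: total
#' antisense reads over total reads, pooled across all genes.
#'
#' @param counts data frame with `gene`, `sense`, `antisense`.
#' @return a single proportion in `[0, 1]`.
#' @export
global_antisense_proportion <- function(counts) {
  stopifnot(all(c("sense", "antisense") %in% names(counts)))
  if (any(counts$sense < 0 | counts$antisense < 0)) {
    stop("negative read counts")
  }
  tot <- sum(counts$sense) + sum(counts$antisense)
  if (tot == 0) stop("all gene counts are zero; cannot estimate a global antisense proportion")
  sum(counts$antisense) / tot
}

#' Exact binomial test for excess antisense transcription per gene
#'
#' For each gene, the one-sided upper-tail exact binomial p-value
#' `P(X >= antisense | n = sense + antisense, p0)` against the globally
#' estimated antisense proportion, followed by Benjamini-Hochberg
#' correction across the tested genes. Genes with zero total reads are
#' excluded from testing and from the BH denominator (their count is
#' recorded). One-sided because the trap hypothesis is antisense
#' *excess*, not depletion.
#'
#' @param counts data frame with `gene`, `sense`, `antisense`.
#' @param p0 null antisense proportion, in (0, 1); typically
#'   [global_antisense_proportion()].
#' @param alpha FDR level (default 0.05).
#' @return data frame `gene`, `sense`, `antisense`, `total`, `p_value`,
#'   `q_value`, `significant`, `global_p0`, with attribute
#'   `n_zero_excluded`.
#' @export
binomial_antisense_test <- function(counts, p0, alpha = 0.05) {
  if (!is.numeric(p0) || length(p0) != 1 || p0 <= 0 || p0 >= 1) {
    stop("p0 must be a single proportion strictly inside (0, 1)")
  }
  total <- counts$sense + counts$antisense
  zero <- total == 0
  tested <- counts[!zero, , drop = FALSE]
  n <- tested$sense + tested$antisense
  # upper tail including the observed count
  p <- pbinom(tested$antisense - 1, n, p0, lower.tail = FALSE)
  q <- p.adjust(p, "BH")
  out <- data.frame(gene = tested$gene, sense = tested$sense,
                    antisense = tested$antisense, total = n,
                    p_value = p, q_value = q,
                    significant = q < alpha, global_p0 = p0)
  structure(out, n_zero_excluded = sum(zero))
}

#' Replicate-aware differential antisense expression (Welch t + BH)
#'
#' Welch t-test per gene on log2 antisense RPM between two groups of
#' replicate samples, BH-corrected.
#'
#' @param wt_counts,ko_counts numeric matrices gene x replicate of raw
#'   antisense counts (shared rownames).
#' @param wt_library_sizes,ko_library_sizes per-replicate library sizes.
#' @param alpha FDR level (default 0.05).
#' @return data frame `gene`, `t`, `p`, `q`, `direction`, `significant`.
#' @export
differential_antisense <- function(wt_counts, ko_counts,
                                   wt_library_sizes, ko_library_sizes,
                                   alpha = 0.05) {
  if (ncol(wt_counts) < 2 || ncol(ko_counts) < 2) {
    stop("need >= 2 replicates per group")
  }
  stopifnot(identical(rownames(wt_counts), rownames(ko_counts)))
  wt <- log2(sweep(wt_counts, 2, wt_library_sizes / 1e6, "/") + 1)
  ko <- log2(sweep(ko_counts, 2, ko_library_sizes / 1e6, "/") + 1)
  res <- lapply(seq_len(nrow(wt)), function(i) {
    w <- welch_t(ko[i, ], wt[i, ])
    data.frame(gene = rownames(wt)[i], t = w$t, p = w$p,
               direction = w$direction)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, "BH")
  out$significant <- out$q < alpha
  out[c("gene", "t", "p", "q", "direction", "significant")]
}

#' Pervasive-antisense gene set and KO-vs-WT summary
#'
#' The trap gene set is the intersection of the binomial-significant
#' genes and the differential-significant genes (direction > 0, i.e.
#' antisense gain in KO). The summary reports the antisense read
#' proportion in each group and both their difference and ratio.
#'
#' @param binomial_result result of [binomial_antisense_test()] on the
#'   KO counts.
#' @param differential_result result of [differential_antisense()].
#' @param wt_counts,ko_counts data frames `gene`, `sense`, `antisense`
#'   (pooled per group) for the proportion summary; optional.
#' @return a list with `genes` (character), `n_binomial`,
#'   `n_differential`, and `summary` (antisense proportions, difference,
#'   ratio) when pooled counts are supplied.
#' @export
antisense_gene_set <- function(binomial_result, differential_result,
                               wt_counts = NULL, ko_counts = NULL) {
  b <- binomial_result$gene[binomial_result$significant]
  d <- differential_result$gene[differential_result$significant &
                                  differential_result$direction > 0]
  genes <- intersect(b, d)
  out <- list(genes = genes, n_binomial = length(b),
              n_differential = length(d))
  if (!is.null(wt_counts) && !is.null(ko_counts)) {
    p_wt <- global_antisense_proportion(wt_counts)
    p_ko <- global_antisense_proportion(ko_counts)
    out$summary <- data.frame(
      antisense_prop_wt = p_wt, antisense_prop_ko = p_ko,
      difference = p_ko - p_wt,
      ratio = if (p_wt > 0) p_ko / p_wt else NA_real_
    )
  }
  out
}

#' Gene-level sense/antisense counts from an overlap count table
#'
#' Reshapes [count_overlaps()] output (run once per orientation) into
#' the `gene`, `sense`, `antisense` layout of the antisense tests.
#'
#' @param sense_counts,antisense_counts long count tables for one sample
#'   (or pooled samples) from [count_overlaps()].
#' @return data frame `gene`, `sense`, `antisense`.
#' @export
gene_orientation_counts <- function(sense_counts, antisense_counts) {
  s <- aggregate(count ~ feature, sense_counts, sum)
  a <- aggregate(count ~ feature, antisense_counts, sum)
  stopifnot(identical(sort(s$feature), sort(a$feature)))
  a <- a[match(s$feature, a$feature), ]
  data.frame(gene = s$feature, sense = s$count, antisense = a$count)
}
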