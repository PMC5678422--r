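#' Methylation in consecutive 50-CpG windows
#'
#' CpGs are filtered to coverage >= `min_cov`, then grouped per
#' chromosome, left to right, into non-overlapping blocks of
#' `window_cpgs` consecutive qualifying sites. The window percentage is
#' call-weighted: `100 * sum(meth) / sum(meth + unmeth)` within the
#' block. Terminal blocks with fewer than `window_cpgs` sites are
#' dropped.
#'
#' @param calls methylation call data frame (`chrom`, `pos`,
#'   `count_meth`, `count_unmeth`), sorted by position within each
#'   chromosome.
#' @param window_cpgs CpGs per window (default 50).
#' @param min_cov minimum per-CpG coverage (default 3).
#' @return data frame `chrom`, `start`, `end`, `n_cpgs`,
#'   `percent_methylation`, with attributes `n_cpgs_input`,
#'   `n_cpgs_low_coverage`.
#' @export
window_methylation <- function(calls, window_cpgs = 50, min_cov = 3) {
  unsorted <- vapply(split(calls$pos, calls$chrom), is.unsorted, TRUE)
  if (any(unsorted)) {
    stop("calls must be sorted by position within chromosome (unsorted: ",
         paste(names(unsorted)[unsorted], collapse = ", "), ")")
  }
  n_input <- nrow(calls)
  cov <- calls$count_meth + calls$count_unmeth
  keep <- cov >= min_cov
  calls <- calls[keep, , drop = FALSE]
  res <- lapply(split(calls, calls$chrom), function(df) {
    n_win <- nrow(df) %/% window_cpgs
    if (n_win == 0) return(NULL)
    idx <- seq_len(n_win * window_cpgs)
    win <- factor(rep(seq_len(n_win), each = window_cpgs),
                  levels = seq_len(n_win))
    meth <- tapply(df$count_meth[idx], win, sum)
    tot <- tapply(df$count_meth[idx] + df$count_unmeth[idx], win, sum)
    data.frame(chrom = df$chrom[1],
               start = tapply(df$pos[idx], win, min),
               end = tapply(df$pos[idx], win, max) + 1L,
               n_cpgs = window_cpgs,
               percent_methylation = 100 * meth / tot)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      percent_methylation = numeric(0))
  }
  rownames(out) <- NULL
  structure(out, n_cpgs_input = n_input, n_cpgs_low_coverage = sum(!keep))
}

#' Feature-level methylation (CpG-weighted)
#'
#' Per feature, the mean over qualifying CpGs (coverage >= `min_cov`) of
#' the per-CpG methylation percentage — each CpG contributes equally
#' regardless of its coverage, unlike the call-weighted window
#' quantitation. Features with fewer than `min_cpgs` qualifying CpGs are
#' reported as missing (NA).
#'
#' @param calls methylation call data frame.
#' @param features feature data frame with `id`.
#' @param min_cpgs minimum qualifying CpGs per feature (default 50).
#' @param min_cov minimum per-CpG coverage (default 3).
#' @return data frame `id`, `n_cpgs`, `percent_methylation`.
#' @export
feature_methylation <- function(calls, features, min_cpgs = 50,
                                min_cov = 3) {
  cov <- calls$count_meth + calls$count_unmeth
  calls <- calls[cov >= min_cov, , drop = FALSE]
  out <- data.frame(id = features$id, n_cpgs = 0L,
                    percent_methylation = NA_real_)
  if (nrow(calls) && nrow(features)) {
    site_gr <- GenomicRanges::GRanges(
      calls$chrom, IRanges::IRanges(calls$pos + 1L, width = 1L))
    hits <- .find_overlaps(site_gr, .gr(features))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    pct <- 100 * calls$count_meth[qh] /
      (calls$count_meth[qh] + calls$count_unmeth[qh])
    n <- tapply(pct, sh, length)
    m <- tapply(pct, sh, mean)
    ii <- as.integer(names(n))
    out$n_cpgs[ii] <- as.integer(n)
    out$percent_methylation[ii] <- ifelse(n >= min_cpgs, m, NA_real_)
  }
  out
}

#' TE-class methylation with the minimum-observation filter
#'
#' Per class and sample, 100 x summed methylated calls over summed total
#' calls across all instances. A class is reported only when its total
#' observation count (methylated + unmethylated calls) reaches `min_obs`
#' in *every* sample of the comparison.
#'
#' @param call_sets named list of methylation call data frames, one per
#'   sample.
#' @param tes TE annotation (after the genic-exclusion filter).
#' @param min_obs minimum observations per class per sample
#'   (default 1000).
#' @return a classes x samples matrix of methylation percentages
#'   (classes failing the filter are dropped), with attribute
#'   `observations` (the class x sample observation counts).
#' @export
te_class_methylation <- function(call_sets, tes, min_obs = 1000) {
  stopifnot(is.list(call_sets), length(call_sets) >= 1)
  classes <- sort(unique(tes$class))
  te_gr <- .gr(tes)
  per_sample <- lapply(call_sets, function(calls) {
    site_gr <- GenomicRanges::GRanges(
      calls$chrom, IRanges::IRanges(calls$pos + 1L, width = 1L))
    hits <- .find_overlaps(site_gr, te_gr)
    qh <- S4Vectors::queryHits(hits)
    cls <- tes$class[S4Vectors::subjectHits(hits)]
    meth <- tapply(calls$count_meth[qh], cls, sum)
    tot <- tapply(calls$count_meth[qh] + calls$count_unmeth[qh], cls, sum)
    list(meth = meth, tot = tot)
  })
  obs <- sapply(per_sample, function(x) {
    v <- setNames(rep(0, length(classes)), classes)
    v[names(x$tot)] <- x$tot
    v
  })
  obs <- matrix(obs, nrow = length(classes),
                dimnames = list(classes, names(call_sets)))
  pct <- sapply(per_sample, function(x) {
    v <- setNames(rep(NA_real_, length(classes)), classes)
    v[names(x$tot)] <- 100 * x$meth / x$tot
    v
  })
  pct <- matrix(pct, nrow = length(classes),
                dimnames = list(classes, names(call_sets)))
  keep <- apply(obs >= min_obs, 1, all)
  structure(pct[keep, , drop = FALSE], observations = obs)
}

#' Compare window methylation distributions (Wilcoxon + Bonferroni)
#'
#' Two-sided Wilcoxon rank-sum tests on window percentages for every
#' requested pair of window sets, Bonferroni-corrected over the family
#' of comparisons made in this one invocation. Exact p-values for small
#' tie-free samples, normal approximation with tie correction otherwise
#' (the `stats::wilcox.test` rules).
#'
#' @param window_sets named list of [window_methylation()] results.
#' @param pairs optional 2-column character matrix of set names to
#'   compare; defaults to all pairs.
#' @param alpha family-wise level (default 0.05).
#' @return data frame `a`, `b`, `statistic` (Mann-Whitney U of `a` over
#'   `b`), `p_value`, `p_bonferroni`, `significant`.
#' @export
compare_methylomes <- function(window_sets, pairs = NULL, alpha = 0.05) {
  stopifnot(is.list(window_sets), length(window_sets) >= 2)
  for (nm in names(window_sets)) {
    if (nrow(window_sets[[nm]]) == 0) stop("empty window set: ", nm)
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(names(window_sets), 2))
  }
  res <- apply(pairs, 1, function(pr) {
    x <- window_sets[[pr[1]]]$percent_methylation
    y <- window_sets[[pr[2]]]$percent_methylation
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    data.frame(a = pr[1], b = pr[2], statistic = unname(wt$statistic),
               p_value = wt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out$significant <- out$p_bonferroni < alpha
  out
}
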