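#' Summarise instance-level TE counts to class level
#'
#' Applies the instance-level outlier rule first — an instance is
#' retained only if its count (summed over the orientations present in
#' the table) exceeds `min_count` in at least one sample — then sums
#' counts over the retained instances of each class, separately per
#' orientation. Class length is the summed length of the retained
#' instances. Classes with no retained instance are reported as missing,
#' not zero.
#'
#' @param counts long count table from [count_overlaps()] (one or more
#'   orientations).
#' @param tes TE annotation data frame (`id`, `class`, `start`, `end`),
#'   typically after [filter_tes_near_genes()].
#' @param min_count retention cutoff (default 3: kept if count > 3 in
#'   >= 1 sample).
#' @return a list with `counts` (long class-level table), `class_lengths`
#'   (named bp vector over retained classes), `retained`/`dropped`
#'   (instance ids) and `missing_classes`.
#' @export
summarize_te_classes <- function(counts, tes, min_count = 3) {
  stopifnot(all(c("feature", "sample", "orientation", "count") %in%
                  names(counts)))
  counts <- counts[counts$feature %in% tes$id, , drop = FALSE]
  per_inst <- aggregate(count ~ feature + sample, counts, sum)
  max_per_inst <- tapply(per_inst$count, per_inst$feature, max)
  retained <- names(max_per_inst)[max_per_inst > min_count]
  dropped <- setdiff(unique(counts$feature), retained)

  keep_tes <- tes[tes$id %in% retained, , drop = FALSE]
  class_lengths <- tapply(keep_tes$end - keep_tes$start, keep_tes$class, sum)
  class_lengths <- setNames(as.numeric(class_lengths), names(class_lengths))

  kept <- counts[counts$feature %in% retained, , drop = FALSE]
  kept$class <- tes$class[match(kept$feature, tes$id)]
  cls_counts <- if (nrow(kept)) {
    aggregate(count ~ class + sample + orientation, kept, sum)
  } else {
    data.frame(class = character(0), sample = character(0),
               orientation = character(0), count = integer(0))
  }
  missing_classes <- setdiff(unique(tes$class), names(class_lengths))
  list(counts = cls_counts, class_lengths = class_lengths,
       retained = retained, dropped = dropped,
       missing_classes = missing_classes)
}

#' Length- and library-normalised log2 RPM
#'
#' `log2(count / (library_size / 1e6) / (class_length / 1e3) + 1)`:
#' reads per million library reads per kilobase of summed class length,
#' with a +1 pseudocount so zero counts map to 0.
#'
#' @param class_count raw class count (vectorised).
#' @param library_size total reads in the sample's library.
#' @param class_length summed bp of the class's retained instances.
#' @return numeric log2 RPM value(s).
#' @export
normalize_log2_rpm <- function(class_count, library_size, class_length) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(class_length <= 0)) stop("class_length must be > 0")
  log2(class_count / (library_size / 1e6) / (class_length / 1e3) + 1)
}

#' Per-class Z-scores across samples
#'
#' Standardises each class row to mean 0 and population SD 1 across
#' samples; constant rows (SD = 0) are returned as zeros and flagged.
#'
#' @param mat numeric matrix, classes x samples (e.g. log2 RPM).
#' @return a matrix of the same shape with attribute `constant`
#'   (logical per class).
#' @export
zscore_by_class <- function(mat) {
  if (is.null(dim(mat)) || ncol(mat) < 2) {
    stop("zscore_by_class needs >= 2 samples")
  }
  mu <- rowMeans(mat)
  sdp <- sqrt(rowMeans((mat - mu)^2))  # population SD
  constant <- sdp == 0
  z <- (mat - mu) / ifelse(constant, 1, sdp)
  z[constant, ] <- 0
  structure(z, constant = setNames(constant, rownames(mat)))
}

#' Differential TE-class expression (Welch t + BH)
#'
#' Per class, a Welch two-sample t-test of log2 RPM between the two
#' groups, Benjamini-Hochberg corrected; classes observed in only one
#' group are excluded and listed.
#'
#' @param mat numeric matrix, classes x samples (log2 RPM).
#' @param groups factor/character of length `ncol(mat)` with two levels;
#'   the first level is the reference (direction = sign of
#'   mean(second) - mean(first)).
#' @param alpha significance level on q (default 0.05).
#' @return a data frame `class`, `t`, `p`, `q`, `direction`,
#'   `significant`, with attribute `excluded` naming skipped classes.
#' @export
differential_te <- function(mat, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  if (min(table(groups)) < 2) stop("need >= 2 replicates per group")
  ok <- apply(mat, 1, function(x) {
    sum(is.finite(x[groups == g1])) >= 2 && sum(is.finite(x[groups == g2])) >= 2
  })
  excluded <- rownames(mat)[!ok]
  mat <- mat[ok, , drop = FALSE]
  res <- lapply(rownames(mat), function(cl) {
    w <- welch_t(mat[cl, groups == g2], mat[cl, groups == g1])
    data.frame(class = cl, t = w$t, p = w$p, direction = w$direction)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, "BH")
  out$significant <- out$q < alpha
  out <- out[c("class", "t", "p", "q", "direction", "significant")]
  structure(out, excluded = excluded)
}

# Welch two-sample t via stats::t.test, with defined behaviour for the
# degenerate zero-variance case t.test refuses: identical constant
# groups are null (t = 0, p = 1); constant groups with different means
# are maximally significant (|t| = Inf, p = 0).
welch_t <- function(x, y) {
  d <- mean(x) - mean(y)
  if (sd(x) == 0 && sd(y) == 0) {
    if (d == 0) {
      list(t = 0, p = 1, direction = 0)
    } else {
      list(t = sign(d) * Inf, p = 0, direction = sign(d))
    }
  } else {
    tt <- t.test(x, y, var.equal = FALSE)
    list(t = unname(tt$statistic), p = tt$p.value, direction = sign(d))
  }
}

#' Class x sample log2 RPM matrix from a class summary
#'
#' Convenience wrapper combining [summarize_te_classes()] output with
#' per-sample library sizes into orientation-specific log2 RPM matrices.
#'
#' @param class_summary result of [summarize_te_classes()].
#' @param library_sizes named numeric vector per sample.
#' @param orientation which orientation to extract.
#' @return classes x samples numeric matrix of log2 RPM.
#' @export
class_log2_rpm <- function(class_summary, library_sizes,
                           orientation = "sense") {
  cc <- class_summary$counts
  cc <- cc[cc$orientation == orientation, , drop = FALSE]
  classes <- names(class_summary$class_lengths)
  samples <- names(library_sizes)
  mat <- matrix(0, length(classes), length(samples),
                dimnames = list(classes, samples))
  ij <- cc$class %in% classes & cc$sample %in% samples
  cc <- cc[ij, , drop = FALSE]
  mat[cbind(cc$class, cc$sample)] <- cc$count
  for (s in samples) {
    mat[, s] <- normalize_log2_rpm(mat[, s], library_sizes[[s]],
                                   class_summary$class_lengths[classes])
  }
  mat
}
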