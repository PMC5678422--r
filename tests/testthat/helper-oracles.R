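# Independent oracles: deliberately brute-force / closed-form
# re-derivations that never share code with the implementation.

# Upper-tail exact binomial P(X >= k | n, p) by direct pmf summation.
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

# Benjamini-Hochberg step-up by the textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Welch two-sample t from the formulas.
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Mann-Whitney U of x over y by exhaustive pair comparison.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}

# 5'-5' overlap distribution by exhaustive double loop over read pairs.
oracle_overlap_counts <- function(reads, max_overlap = 30) {
  plus <- reads[reads$strand == "+", , drop = FALSE]
  minus <- reads[reads$strand == "-", , drop = FALSE]
  counts <- setNames(rep(0, max_overlap), seq_len(max_overlap))
  for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
    if (plus$chrom[i] != minus$chrom[j]) next
    if (plus$start[i] >= minus$end[j] || minus$start[j] >= plus$end[i]) next
    o <- (minus$end[j] - 1) - plus$start[i] + 1
    if (o >= 1 && o <= max_overlap) counts[o] <- counts[o] + 1
  }
  counts
}

# Read-feature overlap counting by exhaustive double loop.
oracle_count_overlaps <- function(reads, features, min_mapq = 20,
                                  orientation = "sense") {
  out <- matrix(0L, nrow(features), length(unique(reads$sample)),
                dimnames = list(features$id, sort(unique(reads$sample))))
  for (i in seq_len(nrow(reads))) {
    if (reads$mapq[i] < min_mapq) next
    for (j in seq_len(nrow(features))) {
      if (reads$chrom[i] != features$chrom[j]) next
      if (reads$start[i] >= features$end[j] ||
          features$start[j] >= reads$end[i]) next
      same <- reads$strand[i] == features$strand[j]
      hit <- switch(orientation, sense = same, antisense = !same,
                    both = TRUE)
      if (hit) {
        out[features$id[j], reads$sample[i]] <-
          out[features$id[j], reads$sample[i]] + 1L
      }
    }
  }
  out
}

# Small, fast configuration for unit tests (not the acceptance
# conditions, which use the defaults).
small_config <- function(seed = 42, ...) {
  sim_config(genome_length = 4e5, n_genes = 40, n_te_instances = 12,
             n_mirna_loci = 10, n_rrna_loci = 2,
             rnaseq_library_size = 2e4, smallrna_library_size = 5e4,
             chip_library_size = 5e4, seed = seed, ...)
}

# Truth set for the trap-recovery checks: genes hosting an
# antisense-inserted TE of a class with activation > 1 at `day`.
trap_truth_genes <- function(ann, cfg, day) {
  genic <- ann$tes[!is.na(ann$tes$host_gene), , drop = FALSE]
  anti <- genic$strand !=
    ann$genes$strand[match(genic$host_gene, ann$genes$id)]
  act <- cfg$te_activation[genic$class, as.character(day)] > 1
  unique(genic$host_gene[anti & act])
}

# One full antisense-trap analysis on simulated data; returns the
# recovered gene set plus the truth labels.
run_trap_analysis <- function(seed) {
  cfg <- sim_config(seed = seed)
  ann <- build_genome(cfg)
  d0 <- min(cfg$timepoints); d1 <- max(cfg$timepoints)
  n <- cfg$n_replicates
  days <- setNames(c(rep(d0, n), rep(d1, n)),
                   c(paste0("WT_", seq_len(n)), paste0("KO_", seq_len(n))))
  gcs <- lapply(names(days), function(s) {
    r <- simulate_rnaseq(ann, cfg, s, days[[s]])
    gene_orientation_counts(
      count_overlaps(r, ann$genes, orientation = "sense"),
      count_overlaps(r, ann$genes, orientation = "antisense"))
  })
  names(gcs) <- names(days)
  wt <- grep("^WT", names(days), value = TRUE)
  ko <- grep("^KO", names(days), value = TRUE)
  pool <- function(w) {
    g <- gcs[[w[1]]]
    for (s in w[-1]) {
      g$sense <- g$sense + gcs[[s]]$sense
      g$antisense <- g$antisense + gcs[[s]]$antisense
    }
    g
  }
  ko_pool <- pool(ko)
  bin <- binomial_antisense_test(ko_pool,
                                 global_antisense_proportion(ko_pool))
  amat <- function(w) {
    m <- sapply(w, function(s) gcs[[s]]$antisense)
    rownames(m) <- gcs[[1]]$gene
    m
  }
  libs <- rep(cfg$rnaseq_library_size, n)
  da <- differential_antisense(amat(wt), amat(ko), libs, libs)
  gs <- antisense_gene_set(bin, da, pool(wt), ko_pool)
  list(genes = gs$genes, truth = trap_truth_genes(ann, cfg, d1),
       counts = gcs)
}
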