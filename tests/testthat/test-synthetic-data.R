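test_that("configuration invariants are enforced", {
  expect_error(sim_config(antisense_insertion_prob = 1.2), "\\[0,1\\]")
  expect_error(sim_config(five_prime_u_prob = -0.1), "\\[0,1\\]")
  expect_error(sim_config(sirna_length_dist = c("22" = 0.9)), "sum to 1")
  expect_error(sim_config(meth_means = c("0" = 0.85)), "timepoint")
  expect_error(sim_config(smallrna_mirna_fraction = 0.95,
                          smallrna_rrna_fraction = 0.04,
                          smallrna_te_fraction = 0.04), "exceed 1")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("genome layout honours non-overlap and the 2 kb intergenic margin", {
  ann <- build_genome(small_config())
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start), ]
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  expect_true(all(ann$tes$start >= 0))
  expect_true(all(ann$tes$end <= ann$chrom_sizes[ann$tes$chrom]))
  # intergenic TEs are what survives the genic-exclusion filter
  intergenic <- ann$tes[is.na(ann$tes$host_gene), ]
  kept <- filter_tes_near_genes(ann$tes, ann$genes, margin = 2000)
  expect_setequal(kept$id, intergenic$id)
})

test_that("genic TE orientation follows the antisense insertion probability", {
  ann <- build_genome(small_config(antisense_insertion_prob = 1))
  genic <- ann$tes[!is.na(ann$tes$host_gene), ]
  host_strand <- ann$genes$strand[match(genic$host_gene, ann$genes$id)]
  expect_true(all(genic$strand != host_strand))

  ann0 <- build_genome(small_config(antisense_insertion_prob = 0))
  genic0 <- ann0$tes[!is.na(ann0$tes$host_gene), ]
  host0 <- ann0$genes$strand[match(genic0$host_gene, ann0$genes$id)]
  expect_true(all(genic0$strand == host0))

  # default rate: empirical antisense fraction consistent with 0.7 at
  # the 99% level (exact binomial)
  annd <- build_genome(sim_config(seed = 1))
  genicd <- annd$tes[!is.na(annd$tes$host_gene), ]
  hostd <- annd$genes$strand[match(genicd$host_gene, annd$genes$id)]
  k <- sum(genicd$strand != hostd)
  expect_gt(binom.test(k, nrow(genicd), 0.7)$p.value, 0.01)
})

test_that("generation is reproducible and seed-sensitive", {
  a <- build_genome(small_config(seed = 7))
  b <- build_genome(small_config(seed = 7))
  c <- build_genome(small_config(seed = 8))
  expect_identical(a$genes, b$genes)
  expect_identical(a$tes, b$tes)
  expect_identical(as.character(a$consensus), as.character(b$consensus))
  expect_false(identical(a$tes$start, c$tes$start))

  cfg <- small_config(seed = 7)
  expect_identical(simulate_methylome(a, cfg, "s1", 0),
                   simulate_methylome(b, cfg, "s1", 0))
  expect_false(identical(simulate_methylome(a, cfg, "s1", 0)$count_meth,
                         simulate_methylome(a, cfg, "s2", 0)$count_meth))
  expect_identical(simulate_chip(a, cfg, "s1", "H3K27me3", 0),
                   simulate_chip(b, cfg, "s1", "H3K27me3", 0))
})

test_that("an overfull genome triggers a placement-failure error", {
  expect_error(build_genome(sim_config(genome_length = 5e4, n_genes = 40,
                                       n_te_instances = 12)),
               "too small")
})

test_that("methylome simulation matches configured means and edge cases", {
  cfg1 <- small_config(meth_means = c("0" = 1, "3" = 1, "6" = 1, "9" = 1),
                       iap_meth_offset = 0)
  ann <- build_genome(cfg1)
  m <- simulate_methylome(ann, cfg1, "s", 0)
  expect_true(all(m$count_unmeth == 0))

  cfg0 <- small_config(meth_means = c("0" = 0, "3" = 0, "6" = 0, "9" = 0),
                       iap_meth_offset = 0)
  m0 <- simulate_methylome(build_genome(cfg0), cfg0, "s", 0)
  expect_true(all(m0$count_meth == 0))

  expect_error(simulate_methylome(ann, cfg1, "s", 4), "0, 3, 6, 9")

  # Monte-Carlo recovery of the configured day-0 mean site rate
  cfgd <- sim_config(seed = 11)
  md <- simulate_methylome(build_genome(cfgd), cfgd, "s", 0)
  cov <- md$count_meth + md$count_unmeth
  rate <- 100 * sum(md$count_meth) / sum(cov)
  expect_lt(abs(rate - 85), 1.5)
})

test_that("RNA-seq reads follow source strands and the activation model", {
  act0 <- default_act <- sim_config()$te_activation
  act0[] <- 0
  cfg <- small_config(te_activation = act0, antisense_background = 0)
  ann <- build_genome(cfg)
  r <- simulate_rnaseq(ann, cfg, "s", 9)
  expect_false(any(r$source_type %in% rownames(act0)))
  gene_strand <- ann$genes$strand[match(r$source, ann$genes$id)]
  expect_true(all(r$strand == gene_strand))
  expect_equal(nrow(r), cfg$rnaseq_library_size)

  # a gene with an antisense activated TE acquires reads on both strands
  cfg2 <- sim_config(seed = 3)
  ann2 <- build_genome(cfg2)
  truth <- trap_truth_genes(ann2, cfg2, 9)
  r2 <- simulate_rnaseq(ann2, cfg2, "s", 9)
  g <- ann2$genes[ann2$genes$id == truth[1], ]
  inside <- r2[r2$chrom == g$chrom & r2$start < g$end & r2$end > g$start, ]
  expect_setequal(unique(inside$strand), c("+", "-"))

  # MAPQ low fraction close to its configured value
  expect_lt(abs(mean(r2$mapq < 20) - cfg2$mapq_low_fraction), 0.01)
})

test_that("activation ratio across days matches the Poisson-thinning expectation", {
  cfg <- sim_config(seed = 4)
  ann <- build_genome(cfg)
  # independent expectation: explicit source-weight arithmetic
  weight_total <- function(day) {
    coup <- function(cl) {
      if (cl %in% cfg$meth_insensitive_classes) return(1)
      m <- cfg$meth_means[[as.character(day)]]
      if (cl == "IAP-like") m <- min(1, m + cfg$iap_meth_offset)
      max(1 - m, cfg$basal_expression_floor)
    }
    te_w <- sum(cfg$te_expr_scale * ann$tes$base_expr *
                  cfg$te_activation[ann$tes$class, as.character(day)] *
                  vapply(ann$tes$class, coup, 0))
    sum(ann$genes$base_expr) + te_w
  }
  iap_w <- function(day) {
    iap <- ann$tes[ann$tes$class == "IAP-like", ]
    m <- min(1, cfg$meth_means[[as.character(day)]] + cfg$iap_meth_offset)
    sum(cfg$te_expr_scale * iap$base_expr *
          cfg$te_activation["IAP-like", as.character(day)] *
          max(1 - m, cfg$basal_expression_floor))
  }
  expected_ratio <- (iap_w(9) / weight_total(9)) /
    (iap_w(0) / weight_total(0))
  n9 <- sum(simulate_rnaseq(ann, cfg, "a", 9)$source_type == "IAP-like")
  n0 <- sum(simulate_rnaseq(ann, cfg, "b", 0)$source_type == "IAP-like")
  expect_lt(abs(n9 / n0 - expected_ratio) / expected_ratio, 0.25)
})

test_that("small RNA libraries have the configured composition and geometry", {
  cfg <- sim_config(seed = 2)
  ann <- build_genome(cfg)
  sr <- simulate_smallrna(ann, cfg, "ago2", 9)
  expect_equal(nrow(sr), cfg$smallrna_library_size)
  expect_true(all(sr$start >= 0 & sr$end <= ann$chrom_sizes[sr$chrom]))
  expect_true(all(nchar(sr$sequence) == sr$length))

  te <- sr[startsWith(sr$source_type, "TE:"), ]
  u <- mean(substring(te$sequence, 1, 1) == "T")
  expect_gt(binom.test(sum(substring(te$sequence, 1, 1) == "T"),
                       nrow(te), cfg$five_prime_u_prob)$p.value, 0.01)

  # no activation => no TE-derived duplexes
  act0 <- cfg$te_activation; act0[] <- 0
  cfg0 <- small_config(te_activation = act0)
  sr0 <- simulate_smallrna(build_genome(cfg0), cfg0, "s", 9)
  expect_false(any(startsWith(sr0$source_type, "TE:")))

  # fixed 22-nt guides without overhang pair with a 22-nt 5'-5' overlap
  cfg22 <- small_config(sirna_length_dist = c("22" = 1),
                        duplex_overhang = 0)
  ann22 <- build_genome(cfg22)
  sr22 <- simulate_smallrna(ann22, cfg22, "s", 9)
  te22 <- sr22[startsWith(sr22$source_type, "TE:"), ]
  sig <- overlap_signature(te22)
  expect_identical(sig$mode, 22L)
})

test_that("ChIP tiles scale with configured class enrichment", {
  cfg <- sim_config(seed = 6)
  ann <- build_genome(cfg)
  expect_error(simulate_chip(ann, cfg, "s", "H3K4me3", 0), "unknown mark")

  # multiplier 2 on IAP-like tiles: count ratio near 2
  enr <- cfg$chip_enrichment
  enr$H3K9me3 <- list("IAP-like" = c("0" = 2, "3" = 1, "6" = 1, "9" = 1))
  cfg2 <- sim_config(seed = 6, chip_enrichment = enr)
  tiles <- simulate_chip(ann, cfg2, "s", "H3K9me3", 0)
  iap <- ann$tes[ann$tes$class == "IAP-like", ]
  hit <- IRanges::overlapsAny(
    GenomicRanges::GRanges(tiles$chrom,
                           IRanges::IRanges(tiles$start + 1, tiles$end)),
    GenomicRanges::GRanges(iap$chrom,
                           IRanges::IRanges(iap$start + 1, iap$end)))
  other <- ann$tes[ann$tes$class != "IAP-like", ]
  hit_other <- IRanges::overlapsAny(
    GenomicRanges::GRanges(tiles$chrom,
                           IRanges::IRanges(tiles$start + 1, tiles$end)),
    GenomicRanges::GRanges(other$chrom,
                           IRanges::IRanges(other$start + 1, other$end)))
  ratio <- mean(tiles$count[hit]) / mean(tiles$count[!hit & !hit_other])
  expect_lt(abs(ratio - 2), 0.2)

  # all-unity multipliers: enrichment flat
  enr1 <- list()
  cfg1 <- sim_config(seed = 6, chip_enrichment = enr1)
  t1 <- tile_log2_obs_exp(simulate_chip(ann, cfg1, "s", "H3K27me3", 9))
  expect_lt(abs(mean(t1$log2_oe)), 0.05)
})
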