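toy_reads <- function(start, len, strand, chrom = "c1", seq = NULL) {
  data.frame(chrom = chrom, start = start, end = start + len,
             strand = strand, length = len,
             sequence = if (is.null(seq)) strrep("A", len) else seq)
}

test_that("length filtering uses inclusive bounds and preserves order", {
  r <- toy_reads(c(0, 10, 20, 30, 40), c(19, 20, 22, 24, 25),
                 rep("+", 5))
  f <- filter_by_length(r)
  expect_equal(f$length, c(20, 22, 24))
  expect_equal(attr(f, "n_removed"), 2L)
  expect_equal(nrow(filter_by_length(r[0, ])), 0)
  expect_error(filter_by_length(r, 25, 20), "min_nt")
})

test_that("hierarchical exclusion partitions with stated precedence", {
  rrna <- data.frame(chrom = "c1", start = 100L, end = 200L)
  mirna <- data.frame(chrom = "c1", start = 150L, end = 300L)
  reps <- data.frame(chrom = "c1", start = 500L, end = 600L)
  # read overlapping both rRNA and miRNA annotation: binned rRNA
  both <- toy_reads(160, 22, "+")
  part <- hierarchical_exclusion(both, rrna, mirna, reps)
  expect_equal(nrow(part$rRNA), 1)
  expect_equal(nrow(part$miRNA), 0)
  # read overlapping nothing: non-repeat genome bin
  nowhere <- toy_reads(900, 22, "+")
  expect_equal(nrow(hierarchical_exclusion(nowhere, rrna, mirna,
                                           reps)$genome), 1)

  # 30 random reads match brute-force rule application and partition
  set.seed(31)
  rnd <- toy_reads(sample(0:980, 30), 20L, sample(c("+", "-"), 30, TRUE))
  part2 <- hierarchical_exclusion(rnd, rrna, mirna, reps)
  expect_equal(sum(vapply(part2, nrow, 0L)), 30L)
  ov <- function(r, a) r$start < a$end & a$start < r$end
  for (i in seq_len(30)) {
    r <- rnd[i, ]
    bin <- if (ov(r, rrna)) "rRNA" else if (ov(r, mirna)) "miRNA"
      else if (!ov(r, reps)) "genome" else "repeat_assignable"
    expect_true(r$start %in% part2[[bin]]$start)
  }
  # idempotence: re-partitioning any bin keeps its members in place
  again <- hierarchical_exclusion(part2$genome, rrna, mirna, reps)
  expect_equal(nrow(again$genome), nrow(part2$genome))
})

test_that("length/strand distribution conserves totals and marginals", {
  r <- toy_reads(c(0, 40, 80, 120), c(22, 22, 21, 22),
                 c("+", "-", "+", "+"))
  tab <- length_strand_distribution(r)
  expect_equal(sum(tab), nrow(r))
  expect_equal(as.vector(rowSums(tab)), as.vector(table(r$length)))
  expect_equal(unname(tab["22", "+"]), 2L)
})

test_that("5' composition tallies the first base with U for T", {
  r <- toy_reads(seq(0, 70, 10), 20L, "+",
                 seq = c("TAAA", "TCCC", "AGGG", "CTTT", "TGGG", "GAAA",
                         "TTTT", "TACG"))
  comp <- five_prime_composition(r)
  expect_equal(unname(comp["U"]), 5 / 8)
  expect_equal(unname(comp["A"]), 1 / 8)
  expect_equal(sum(comp), 1)
  expect_error(five_prime_composition(r[0, ]), "empty")
})

test_that("overlap signature reproduces duplex geometry and the oracle", {
  # 22-nt sense at [x, x+22), 22-nt antisense at [x-2, x+20): overlap 20
  x <- 1000L
  duplex <- rbind(toy_reads(x, 22L, "+"), toy_reads(x - 2L, 22L, "-"))
  sig <- overlap_signature(duplex)
  expect_equal(sig$mode, 20L)
  expect_equal(unname(sig$counts["20"]), 1)
  expect_equal(sum(sig$counts), 1)

  # same-strand reads only: empty signature, flagged
  ss <- overlap_signature(rbind(toy_reads(0, 22L, "+"),
                                toy_reads(5, 22L, "+")))
  expect_true(ss$empty)
  expect_true(is.na(ss$mode))

  # 6 hand-placed reads vs exhaustive pairing
  six <- rbind(toy_reads(c(100, 130, 500), c(22, 21, 24), "+"),
               toy_reads(c(98, 125, 140), c(22, 23, 20), "-"))
  got <- overlap_signature(six)
  expect_equal(got$counts, oracle_overlap_counts(six))

  # z-score of the mode is positive when one length dominates a
  # non-degenerate background
  set.seed(77)
  bg <- toy_reads(sample(0:1000, 60, replace = TRUE),
                  sample(20:24, 60, replace = TRUE),
                  sample(c("+", "-"), 60, replace = TRUE))
  many <- rbind(bg, do.call(rbind, lapply(seq(2000, 6000, 50), function(s) {
    rbind(toy_reads(s, 22L, "+"), toy_reads(s - 2L, 22L, "-"))
  })))
  sigm <- overlap_signature(many)
  expect_identical(sigm$mode, 20L)
  expect_gt(sigm$zscores[as.character(sigm$mode)], 0)
})

test_that("consensus profiles pile up coverage exactly", {
  r <- data.frame(cpos = 10L, length = 22L)
  cov <- consensus_profile(r, 100L)
  expect_equal(which(cov == 1L), 11:32)
  expect_equal(sum(cov), 22)

  set.seed(8)
  r5 <- data.frame(cpos = c(0L, 5L, 5L, 60L, 78L),
                   length = c(20L, 22L, 24L, 21L, 22L))
  cov5 <- consensus_profile(r5, 100L)
  manual <- integer(100)
  for (i in 1:5) {
    manual[(r5$cpos[i] + 1):(r5$cpos[i] + r5$length[i])] <-
      manual[(r5$cpos[i] + 1):(r5$cpos[i] + r5$length[i])] + 1L
  }
  expect_equal(cov5, manual)
  expect_equal(sum(cov5), sum(r5$length))
  expect_error(consensus_profile(data.frame(cpos = 90L, length = 22L), 100L),
               "bounds")
})

test_that("exact substring matching locates reads on a consensus", {
  cfg <- small_config()
  cons <- build_genome(cfg)$consensus[["IAP-like"]]
  cons_chr <- as.character(cons)
  offs <- c(0L, 100L, 731L)
  seqs <- substring(cons_chr, offs + 1L, offs + 22L)
  got <- match_to_consensus(seqs, cons)
  expect_equal(got, offs)
  # minus-strand reads (reverse complement) are found too
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs[2])))
  expect_equal(match_to_consensus(rc, cons), offs[2])
  # a foreign sequence has no match
  expect_true(is.na(match_to_consensus(strrep("ACGT", 6), cons)))
})

test_that("class-level small RNA comparison applies Student's t with tiers", {
  n_by_sample <- c(a1 = 10, a2 = 14, b1 = 60, b2 = 70)
  reads <- do.call(rbind, lapply(names(n_by_sample), function(s) {
    data.frame(te_class = c(rep("IAP-like", n_by_sample[[s]]),
                            rep("SINE", 20)),
               sample = s)
  }))
  libs <- setNames(rep(1e5, 4), names(n_by_sample))
  grp <- setNames(c("d0", "d0", "d8", "d8"), names(libs))
  out <- te_class_smallrna(reads, libs, grp)
  expect_equal(unname(out$rpm["IAP-like", "b1"]), 60 / 0.1)
  iap <- out$tests[out$tests$class == "IAP-like", ]
  # Student's t (equal variance) on 2 vs 2 RPM values
  x <- c(600, 700); y <- c(100, 140)
  expect_equal(iap$t, unname(t.test(x, y, var.equal = TRUE)$statistic))
  sine <- out$tests[out$tests$class == "SINE", ]
  expect_equal(sine$tier, "")
  expect_error(te_class_smallrna(reads, libs,
                                 setNames(c("a", "b", "b", "b"),
                                          names(libs))), "replicates")
})
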