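test_that("BED6 round-trips and rejects malformed lines", {
  df <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(0L, 150L, 10L), end = c(100L, 300L, 11L),
                   name = c("a", "b", "c"), score = c(1, 2.5, 0),
                   strand = c("+", "-", "+"))
  path <- tempfile(fileext = ".bed")
  write_bed(df, path)
  expect_equal(read_bed(path), df)

  bad <- tempfile()
  writeLines(c("chr1\t0\t100\tx\t0\t+", "chr1\t100\t100\ty\t0\t+"), bad)
  expect_error(read_bed(bad), "line 2")
  writeLines("chr1\t10\t20", bad)
  expect_error(read_bed(bad), "6 tab-separated fields")
  writeLines("chr1\t-5\t20\tx\t0\t+", bad)
  expect_error(read_bed(bad), "0 <= start < end")
  writeLines("chr1\t5\t20\tx\t0\t*", bad)
  expect_error(read_bed(bad), "strand")
  expect_error(write_bed(data.frame(chrom = "chr1", start = 5, end = 5),
                         tempfile()), "start < end")
})

test_that("GFF3 genes convert between 1-based closed and 0-based half-open", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t101\t200\t.\t+\t.\tID=geneA"), path)
  g <- read_gff3_genes(path)
  expect_equal(g$start, 100)
  expect_equal(g$end, 200)

  genes <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 500L),
                      end = c(1000L, 900L), strand = c("+", "-"),
                      id = c("g1", "g2"))
  out <- tempfile(fileext = ".gff3")
  write_gff3_genes(genes, out)
  back <- read_gff3_genes(out)
  expect_equal(back[order(back$id), ], genes, ignore_attr = TRUE)
})

test_that("methylation coverage files round-trip with 1-based positions", {
  calls <- data.frame(chrom = "chr1", pos = c(10L, 25L, 99L),
                      count_meth = c(3L, 0L, 5L),
                      count_unmeth = c(1L, 4L, 0L))
  path <- tempfile(fileext = ".cov")
  write_meth_coverage(calls, path)
  raw <- read.table(path, sep = "\t")
  expect_equal(raw$V2, calls$pos + 1L)  # 1-based on disk
  expect_equal(read_meth_coverage(path), calls)
})

test_that("read tables round-trip and honour the strand convention switch", {
  reads <- data.frame(chrom = "chr1", start = c(5L, 50L), end = c(25L, 80L),
                      strand = c("+", "-"), mapq = c(42L, 7L),
                      sample = c("s1", "s1"))
  path <- tempfile(fileext = ".bed")
  write_reads(reads, path)
  expect_equal(read_reads(path), reads)
  rev <- read_reads(path, strand_convention = "reverse")
  expect_equal(rev$strand, c("-", "+"))
})

test_that("the genic-exclusion filter matches brute-force interval logic", {
  gene <- data.frame(chrom = "chr1", start = 10000L, end = 12000L)
  tes <- data.frame(chrom = "chr1",
                    start = c(10500L, 7999L, 8000L, 14000L, 13999L),
                    end =   c(10600L, 8000L, 8100L, 14100L, 14000L),
                    id = paste0("te", 1:5))
  kept <- filter_tes_near_genes(tes, gene, margin = 2000)
  # brute force: intersect [gene.start-2000, gene.end+2000)
  lo <- 10000 - 2000; hi <- 12000 + 2000
  manual <- tes[!(tes$start < hi & tes$end > lo), ]
  expect_equal(kept$id, manual$id)
  # half-open boundaries: te2 (ends exactly at the margin start) and
  # te4 (starts exactly at gene end + 2000) survive
  expect_setequal(kept$id, c("te2", "te4"))
  expect_equal(attr(kept, "n_removed"), 3L)

  # margin 0 removes exactly gene-body intersectors
  kept0 <- filter_tes_near_genes(tes, gene, margin = 0)
  expect_setequal(kept0$id, c("te2", "te3", "te4", "te5"))
  expect_error(filter_tes_near_genes(tes, gene, margin = -1), ">= 0")
})

test_that("genome tiling is exact and conserves chromosome span", {
  tl <- tile_genome(c(chrA = 2500), width = 1000)
  expect_equal(tl$start, c(0, 1000, 2000))
  expect_equal(tl$end, c(1000, 2000, 2500))
  expect_equal(tl$partial, c(FALSE, FALSE, TRUE))

  sizes <- c(chr1 = 123456, chr2 = 5000, chr3 = 999)
  tl2 <- tile_genome(sizes, width = 1000)
  span <- tapply(tl2$end - tl2$start, tl2$chrom, sum)
  expect_equal(as.numeric(span[names(sizes)]), as.numeric(sizes))
  expect_equal(nrow(tl2), sum(ceiling(sizes / 1000)))
  expect_error(tile_genome(sizes, width = 0), "> 0")
})

test_that("overlap counting equals the exhaustive double loop", {
  set.seed(99)
  features <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                         start = c(100L, 400L, 50L),
                         end = c(300L, 600L, 500L),
                         strand = c("+", "-", "+"),
                         id = c("f1", "f2", "f3"))
  reads <- data.frame(
    chrom = sample(c("chr1", "chr2"), 12, replace = TRUE),
    start = sample(0:550, 12), strand = sample(c("+", "-"), 12, TRUE),
    mapq = sample(c(5, 19, 20, 40), 12, replace = TRUE),
    sample = sample(c("s1", "s2"), 12, replace = TRUE))
  reads$end <- reads$start + 50L
  for (ori in c("sense", "antisense", "both")) {
    got <- count_overlaps(reads, features, orientation = ori)
    want <- oracle_count_overlaps(reads, features, orientation = ori)
    for (i in seq_len(nrow(got))) {
      expect_equal(got$count[i], want[got$feature[i], got$sample[i]],
                   info = paste(ori, got$feature[i], got$sample[i]))
    }
  }
  # a read below the MAPQ cutoff contributes nowhere
  one <- data.frame(chrom = "chr1", start = 150L, end = 200L,
                    strand = "+", mapq = 19L, sample = "s1")
  expect_true(all(count_overlaps(one, features)$count == 0))
  expect_equal(attr(count_overlaps(one, features), "n_mapq_discarded"), 1L)
  # strand orientation: + read over - feature counts antisense only
  r <- data.frame(chrom = "chr1", start = 450L, end = 470L, strand = "+",
                  mapq = 60L, sample = "s1")
  cs <- count_overlaps(r, features, orientation = "sense")
  ca <- count_overlaps(r, features, orientation = "antisense")
  expect_equal(cs$count[cs$feature == "f2"], 0L)
  expect_equal(ca$count[ca$feature == "f2"], 1L)
})

test_that("sense plus antisense equals the orientation-blind recount", {
  cfg <- small_config(seed = 12)
  ann <- build_genome(cfg)
  reads <- simulate_rnaseq(ann, cfg, "s", 9)
  tes <- filter_tes_near_genes(ann$tes, ann$genes)
  s <- count_overlaps(reads, tes, orientation = "sense")
  a <- count_overlaps(reads, tes, orientation = "antisense")
  b <- count_overlaps(reads, tes, orientation = "both")
  expect_equal(s$count + a$count, b$count)
})
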