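#' Read a BED6 file
#'
#' Strict reader: every line must have six tab-separated fields with
#' `0 <= start < end` and strand in `+/-/.`; violations are rejected with
#' the offending line number rather than clamped.
#'
#' @param path file path.
#' @return a data frame `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open, as BED).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6)) {
    stop("malformed BED6 line ", which(nf < 6)[1], " in ", path,
         ": expected 6 tab-separated fields, got ", nf[which(nf < 6)[1]])
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED6 line ", bad[1], " in ", path,
         ": non-integer coordinates")
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop("malformed BED6 line ", bad[1], " in ", path,
         ": requires 0 <= start < end, got [", start[bad[1]], ", ",
         end[bad[1]], ")")
  }
  bad <- which(!m[, 6] %in% c("+", "-", "."))
  if (length(bad)) {
    stop("malformed BED6 line ", bad[1], " in ", path,
         ": invalid strand '", m[bad[1], 6], "'")
  }
  data.frame(chrom = m[, 1], start = start, end = end, name = m[, 4],
             score = suppressWarnings(as.numeric(m[, 5])), strand = m[, 6])
}

#' Write intervals as BED6
#'
#' @param intervals data frame with `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly. `read_bed(write_bed(x))` is the identity
#'   on the six BED columns.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start < 0 | intervals$start >= intervals$end)) {
    stop("invalid interval: requires 0 <= start < end")
  }
  df <- data.frame(
    chrom = intervals$chrom, start = intervals$start, end = intervals$end,
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0,
    strand = if ("strand" %in% names(intervals)) intervals$strand else "."
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write/read TE annotation as BED6 (name = class, score = instance index)
#' @param tes TE data frame as in a `genome_annotation`.
#' @param path file path.
#' @return `read_te_bed` returns a TE data frame with `class` and `id`.
#' @export
write_te_bed <- function(tes, path) {
  write_bed(data.frame(chrom = tes$chrom, start = tes$start, end = tes$end,
                       name = tes$class, score = seq_len(nrow(tes)),
                       strand = tes$strand), path)
}

#' @rdname write_te_bed
#' @export
read_te_bed <- function(path) {
  bed <- read_bed(path)
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             strand = bed$strand, class = bed$name,
             id = sprintf("te%04d", as.integer(bed$score)))
}

#' Write/read gene annotation as GFF3
#'
#' GFF3 is 1-based closed; internal coordinates are 0-based half-open,
#' so a gene at GFF3 `[101, 200]` becomes internal `(100, 200)`.
#' Delegates parsing/formatting to rtracklayer.
#'
#' @param genes gene data frame (`chrom`, `start`, `end`, `strand`, `id`).
#' @param path file path.
#' @return `read_gff3_genes` returns a gene data frame in internal
#'   coordinates.
#' @export
write_gff3_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$id
  S4Vectors::mcols(gr)$source <- "tetrap"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3_genes
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             id = as.character(S4Vectors::mcols(gr)$ID))
}

#' Write/read per-CpG methylation calls (Bismark coverage format)
#'
#' Tab-separated `chrom, start, end, percent, count_meth, count_unmeth`
#' with 1-based positions (start = end = the CpG position); internal
#' positions are 0-based.
#'
#' @param calls data frame `chrom`, `pos`, `count_meth`, `count_unmeth`.
#' @param path file path.
#' @return `read_meth_coverage` returns the internal-call data frame.
#' @export
write_meth_coverage <- function(calls, path) {
  cov <- calls$count_meth + calls$count_unmeth
  pct <- ifelse(cov > 0, 100 * calls$count_meth / cov, 0)
  df <- data.frame(chrom = calls$chrom, start = calls$pos + 1L,
                   end = calls$pos + 1L, percent = round(pct, 6),
                   count_meth = calls$count_meth,
                   count_unmeth = calls$count_unmeth)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_meth_coverage
#' @export
read_meth_coverage <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "percent",
                                 "count_meth", "count_unmeth"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric", "integer", "integer"))
  if (any(df$start < 1 | df$end < df$start)) {
    stop("invalid Bismark-coverage coordinates in ", path,
         " (1-based positions required) at line ",
         which(df$start < 1 | df$end < df$start)[1])
  }
  if (any(df$count_meth < 0 | df$count_unmeth < 0)) {
    stop("negative call counts in ", path)
  }
  data.frame(chrom = df$chrom, pos = df$start - 1L,
             count_meth = df$count_meth, count_unmeth = df$count_unmeth)
}

#' Write/read aligned read records (BED6-like with MAPQ in the score
#' column)
#'
#' @param reads read data frame (`chrom`, `start`, `end`, `strand`,
#'   `mapq`, `sample`).
#' @param path file path.
#' @param strand_convention `"forward"` (read strand = transcript
#'   strand, the synthetic-data convention) or `"reverse"` (dUTP-style
#'   protocols where the sequenced strand is opposite the transcript):
#'   `"reverse"` flips the strand on read.
#' @return `read_reads` returns the read data frame.
#' @export
write_reads <- function(reads, path) {
  write_bed(data.frame(chrom = reads$chrom, start = reads$start,
                       end = reads$end, name = reads$sample,
                       score = reads$mapq, strand = reads$strand), path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path, strand_convention = c("forward", "reverse")) {
  strand_convention <- match.arg(strand_convention)
  bed <- read_bed(path)
  if (any(bed$score < 0)) {
    stop("negative MAPQ in ", path, " at line ", which(bed$score < 0)[1])
  }
  strand <- bed$strand
  if (strand_convention == "reverse") {
    strand <- ifelse(strand == "+", "-", ifelse(strand == "-", "+", strand))
  }
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             strand = strand, mapq = as.integer(bed$score),
             sample = bed$name)
}

#' Write/read count tables (`feature<TAB>sample<TAB>orientation<TAB>count`)
#' @param counts long-format count data frame.
#' @param path file path.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(all(c("feature", "sample", "orientation", "count") %in%
                  names(counts)))
  write.table(counts[c("feature", "sample", "orientation", "count")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE,
             colClasses = c("character", "character", "character",
                            "integer"))
}

#' Write/read tile count tables
#' @param tiles tile data frame with counts.
#' @param path file path.
#' @export
write_tile_counts <- function(tiles, path) {
  write.table(tiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tile_counts
#' @export
read_tile_counts <- function(path) {
  read.table(path, sep = "\t", header = TRUE)
}

#' Write consensus sequences as FASTA
#' @param consensus a named `DNAStringSet` (one entry per TE class).
#' @param path file path.
#' @export
write_consensus_fasta <- function(consensus, path) {
  Biostrings::writeXStringSet(consensus, path)
  invisible(path)
}

#' @rdname write_consensus_fasta
#' @export
read_consensus_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
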