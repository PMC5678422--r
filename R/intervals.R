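#' Remove TEs within a margin of any gene
#'
#' Drops every TE whose interval intersects any
#' `[gene_start - margin, gene_end + margin)` interval, the conservative
#' filter that avoids attributing promoter-driven transcription to the
#' TE itself. Half-open convention: a TE starting exactly at
#' `gene_end + margin` is retained.
#'
#' @param tes TE data frame (0-based half-open `chrom`, `start`, `end`).
#' @param genes gene data frame.
#' @param margin bp margin around genes (default 2000).
#' @return the retained TEs, order preserved, with attribute
#'   `n_removed` recording the discard count.
#' @export
filter_tes_near_genes <- function(tes, genes, margin = 2000) {
  if (margin < 0) stop("margin must be >= 0, got ", margin)
  if (!nrow(tes) || !nrow(genes)) {
    return(structure(tes, n_removed = 0L))
  }
  ext <- data.frame(chrom = genes$chrom,
                    start = pmax(0L, genes$start - as.integer(margin)),
                    end = genes$end + as.integer(margin))
  hit <- .overlaps_any(.gr(tes), .gr(ext))
  out <- tes[!hit, , drop = FALSE]
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Tile the genome into fixed-width windows
#'
#' @param chrom_sizes named integer vector of chromosome sizes.
#' @param width tile width in bp (default 1000).
#' @return a data frame of consecutive non-overlapping tiles `chrom`,
#'   `start`, `end`, `partial` (TRUE for the terminal short tile); the
#'   tiles of each chromosome cover it exactly.
#' @export
tile_genome <- function(chrom_sizes, width = 1000) {
  if (width <= 0) stop("width must be > 0")
  width <- as.integer(width)
  out <- lapply(names(chrom_sizes), function(ch) {
    size <- as.integer(chrom_sizes[[ch]])
    start <- seq.int(0L, size - 1L, by = width)
    end <- pmin(start + width, size)
    data.frame(chrom = ch, start = start, end = end,
               partial = end - start < width)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Count read overlaps with features, by orientation
#'
#' A read counts toward a feature when their intervals intersect and the
#' read's MAPQ is at least `min_mapq` (the operational "uniquely
#' mapped"). `sense` counts reads whose strand equals the feature's,
#' `antisense` the opposite, `both` ignores strand. A read overlapping k
#' features increments all k.
#'
#' @param reads read data frame (`chrom`, `start`, `end`, `strand`,
#'   `mapq`, `sample`).
#' @param features feature data frame with an `id` column.
#' @param min_mapq MAPQ threshold (default 20; reads below are
#'   discarded and counted in the `n_mapq_discarded` attribute).
#' @param orientation `"sense"`, `"antisense"` or `"both"`.
#' @return a long data frame `feature`, `sample`, `orientation`,
#'   `count` covering every feature x sample (zeros included), with
#'   attributes `n_mapq_discarded` and `n_input`.
#' @export
count_overlaps <- function(reads, features, min_mapq = 20,
                           orientation = c("sense", "antisense", "both")) {
  orientation <- match.arg(orientation)
  stopifnot("id" %in% names(features))
  samples <- sort(unique(reads$sample))
  if (!length(samples)) samples <- "sample"
  n_input <- nrow(reads)
  keep <- reads$mapq >= min_mapq
  reads <- reads[keep, , drop = FALSE]

  grid <- expand.grid(feature = features$id, sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$orientation <- orientation
  grid$count <- 0L
  if (nrow(reads) && nrow(features)) {
    hits <- .find_overlaps(.gr(reads), .gr(features))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    same <- reads$strand[qh] == features$strand[sh]
    use <- switch(orientation, sense = same, antisense = !same,
                  both = rep(TRUE, length(qh)))
    if (any(use)) {
      tab <- table(feature = features$id[sh[use]],
                   sample = reads$sample[qh[use]])
      ij <- match(paste(grid$feature, grid$sample),
                  paste(rep(rownames(tab), ncol(tab)),
                        rep(colnames(tab), each = nrow(tab))))
      cnt <- as.vector(tab)[ij]
      grid$count <- ifelse(is.na(cnt), 0L, as.integer(cnt))
    }
  }
  structure(grid, n_mapq_discarded = sum(!keep), n_input = n_input)
}
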