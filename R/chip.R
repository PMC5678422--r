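#' Per-tile log2 observed/expected enrichment
#'
#' The expected count per tile is the count had all reads been uniformly
#' distributed over the genome: `library_size x tile_width /
#' genome_length`, pro-rated for partial terminal tiles. Enrichment is
#' `log2((observed + c) / (expected + c))` with pseudocount `c` so empty
#' tiles are defined.
#'
#' @param tiles tile data frame with `chrom`, `start`, `end`, `count`.
#' @param library_size total reads (defaults to `sum(tiles$count)`).
#' @param genome_length total genome size (defaults to the summed tile
#'   span).
#' @param pseudocount pseudocount `c` (default 1).
#' @return `tiles` with `expected` and `log2_oe` columns; the expected
#'   values sum to `library_size`.
#' @export
tile_log2_obs_exp <- function(tiles, library_size = sum(tiles$count),
                              genome_length = sum(tiles$end - tiles$start),
                              pseudocount = 1) {
  if (genome_length <= 0) stop("genome_length must be > 0")
  width <- tiles$end - tiles$start
  tiles$expected <- library_size * width / genome_length
  tiles$log2_oe <- log2((tiles$count + pseudocount) /
                          (tiles$expected + pseudocount))
  tiles
}

#' TE-class ChIP enrichment across samples, with the 2-fold rule
#'
#' Per class and sample: the mean `log2_oe` over tiles intersecting at
#' least one retained instance of the class (tiles overlapping several
#' classes count toward each), plus per-class Z-scores across samples
#' and, for a designated KO/WT pair, the linear fold-change of mean
#' observed counts over the class tiles with a flag for classes at
#' least `fold_threshold`-fold enriched in KO.
#'
#' @param tile_enrichments named list (per sample) of
#'   [tile_log2_obs_exp()] results sharing one tiling.
#' @param tes retained TE annotation (after the genic-exclusion filter).
#' @param ko,wt sample names for the fold-change comparison (optional).
#' @param fold_threshold linear fold cut (default 2).
#' @return a list with `log2_oe` (classes x samples), `zscores`,
#'   `fold_change` (named per class, KO/WT linear ratio of mean counts)
#'   and `flagged` (logical), the latter two present when `ko`/`wt` are
#'   given. Classes with no overlapping tile are dropped (`missing`).
#' @export
te_class_chip_enrichment <- function(tile_enrichments, tes, ko = NULL,
                                     wt = NULL, fold_threshold = 2) {
  stopifnot(length(tile_enrichments) >= 1)
  ref <- tile_enrichments[[1]][c("chrom", "start", "end")]
  for (te_df in tile_enrichments) {
    stopifnot(identical(te_df[c("chrom", "start", "end")], ref))
  }
  classes <- sort(unique(tes$class))
  tile_gr <- .gr(ref)
  class_tiles <- lapply(classes, function(cl) {
    inst <- tes[tes$class == cl, , drop = FALSE]
    if (!nrow(inst)) return(integer(0))
    which(.overlaps_any(tile_gr, .gr(inst)))
  })
  names(class_tiles) <- classes
  missing <- classes[lengths(class_tiles) == 0]
  classes <- setdiff(classes, missing)

  log2_oe <- sapply(tile_enrichments, function(te_df) {
    vapply(classes, function(cl) mean(te_df$log2_oe[class_tiles[[cl]]]), 0)
  })
  log2_oe <- matrix(log2_oe, nrow = length(classes),
                    dimnames = list(classes, names(tile_enrichments)))
  out <- list(log2_oe = log2_oe, missing = missing)
  if (ncol(log2_oe) >= 2) {
    out$zscores <- zscore_by_class(log2_oe)
  }
  if (!is.null(ko) && !is.null(wt)) {
    stopifnot(ko %in% names(tile_enrichments), wt %in% names(tile_enrichments))
    fc <- vapply(classes, function(cl) {
      idx <- class_tiles[[cl]]
      mean(tile_enrichments[[ko]]$count[idx]) /
        mean(tile_enrichments[[wt]]$count[idx])
    }, 0)
    out$fold_change <- fc
    out$flagged <- fc >= fold_threshold
  }
  out
}
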