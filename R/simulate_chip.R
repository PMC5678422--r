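#' Simulate per-tile ChIP read counts for one mark/sample
#'
#' The genome is tiled at `tile_width` and each tile's count is drawn
#' Poisson with rate `baseline x multiplier`, where the baseline assumes
#' the library is uniformly distributed over the genome (pro-rated for
#' partial terminal tiles) and the multiplier comes from the configured
#' per-mark, per-class, per-day enrichment table for tiles overlapping TE
#' instances of that class (maximum over overlapped classes; 1
#' elsewhere).
#'
#' @inheritParams simulate_methylome
#' @param mark histone mark; must be one of `config$chip_marks`.
#' @return a data frame of tiles: `chrom`, `start`, `end`, `partial`,
#'   `count`, `mark`, `sample`.
#' @export
simulate_chip <- function(annotation, config = annotation$config,
                          sample, mark, day) {
  check_day(config, day)
  if (!mark %in% config$chip_marks) {
    stop("unknown mark '", mark, "'; configured marks: ",
         paste(config$chip_marks, collapse = ", "))
  }
  with_seed(child_seed(config$seed, "chip", sample, mark, day), {
    tiles <- tile_genome(annotation$chrom_sizes, config$tile_width)
    genome_len <- sum(annotation$chrom_sizes)
    base <- config$chip_library_size * (tiles$end - tiles$start) / genome_len
    mult <- rep(1, nrow(tiles))
    enr <- config$chip_enrichment[[mark]]
    if (!is.null(enr)) {
      tile_gr <- .gr(tiles)
      for (cl in names(enr)) {
        m <- enr[[cl]][[as.character(day)]]
        if (is.null(m) || m == 1) next
        inst <- annotation$tes[annotation$tes$class == cl, , drop = FALSE]
        if (!nrow(inst)) next
        hit <- .overlaps_any(tile_gr, .gr(inst))
        mult[hit] <- pmax(mult[hit], m)
      }
    }
    tiles$count <- rpois(nrow(tiles), base * mult)
    tiles$mark <- mark
    tiles$sample <- sample
    tiles
  })
}
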