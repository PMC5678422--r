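#' Simulate a stranded RNA-seq sample
#'
#' Reads are allocated by multinomial sampling over transcription
#' sources: gene bodies on the gene's strand, a small pervasive
#' background on the opposite strand (`antisense_background` of each
#' gene's rate), and TE instances on the TE's strand. A TE's rate is
#' `base_expr x activation[class, day] x max(1 - m(class, day),
#' basal_expression_floor)` where `m` is the class methylation mean for
#' that day — the linear coupling of transcription to methylation loss.
#' Genes hosting an antisense-inserted TE of an activated class thereby
#' acquire reads on both strands (the "trap" signal). Read strand equals
#' transcript strand; a configurable fraction of reads carries MAPQ < 20.
#'
#' @inheritParams simulate_methylome
#' @return a data frame of read records: `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `mapq`, `sample`, plus simulation
#'   truth columns `source` (feature id) and `source_type`
#'   (`gene`, `gene_antisense`, or TE class).
#' @export
simulate_rnaseq <- function(annotation, config = annotation$config,
                            sample, day) {
  check_day(config, day)
  with_seed(child_seed(config$seed, "rnaseq", sample, day), {
    genes <- annotation$genes
    tes <- annotation$tes
    act <- config$te_activation[tes$class, as.character(day)]
    coup <- expression_coupling(config, tes$class, day)
    src <- rbind(
      data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                 strand = genes$strand,
                 w = genes$base_expr * (1 - config$antisense_background),
                 source = genes$id, source_type = "gene"),
      data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                 strand = ifelse(genes$strand == "+", "-", "+"),
                 w = genes$base_expr * config$antisense_background,
                 source = genes$id, source_type = "gene_antisense"),
      data.frame(chrom = tes$chrom, start = tes$start, end = tes$end,
                 strand = tes$strand,
                 w = config$te_expr_scale * tes$base_expr * act * coup,
                 source = tes$id, source_type = tes$class)
    )
    src <- src[src$w > 0, , drop = FALSE]
    n <- as.vector(rmultinom(1, config$rnaseq_library_size, src$w))
    idx <- rep.int(seq_len(nrow(src)), n)
    flen <- src$end[idx] - src$start[idx]
    start <- src$start[idx] + floor(runif(length(idx)) * pmax(flen - 1L, 1L))
    csize <- annotation$chrom_sizes[src$chrom[idx]]
    end <- pmin(start + config$read_length, csize)
    low <- runif(length(idx)) < config$mapq_low_fraction
    mapq <- ifelse(low, sample(0:19, length(idx), replace = TRUE),
                   sample(20:60, length(idx), replace = TRUE))
    out <- data.frame(chrom = src$chrom[idx], start = as.integer(start),
                      end = as.integer(end), strand = src$strand[idx],
                      mapq = as.integer(mapq), sample = sample,
                      source = src$source[idx],
                      source_type = src$source_type[idx])
    rownames(out) <- NULL
    out
  })
}
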