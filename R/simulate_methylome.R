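#' Simulate a bisulfite methylome for one sample/day
#'
#' CpG sites are laid on a fixed grid (density `cpg_density`, default one
#' site per 100 bp). Per-site coverage is Poisson(`coverage_mean`);
#' methylated calls are Binomial(coverage, site rate) with the site rate
#' drawn from a Beta distribution centred on the day's global mean
#' (concentration `beta_concentration`). CpGs falling inside IAP-like TE
#' instances use the offset mean, emulating the relative demethylation
#' resistance of IAPs.
#'
#' @param annotation a [build_genome()] result.
#' @param config the [sim_config()] (defaults to the one stored in
#'   `annotation`).
#' @param sample sample identifier (also keys the RNG stream).
#' @param day timepoint; must be one of `config$timepoints`.
#' @return a data frame with `chrom`, `pos` (0-based), `count_meth`,
#'   `count_unmeth`, `sample` — one row per CpG site.
#' @export
simulate_methylome <- function(annotation, config = annotation$config,
                               sample, day) {
  check_day(config, day)
  with_seed(child_seed(config$seed, "methylome", sample, day), {
    step <- round(1 / config$cpg_density)
    sites <- do.call(rbind, lapply(names(annotation$chrom_sizes), function(ch) {
      pos <- seq(step %/% 2, annotation$chrom_sizes[[ch]] - 1, by = step)
      data.frame(chrom = ch, pos = as.integer(pos))
    }))
    iap <- annotation$tes[annotation$tes$class == "IAP-like", , drop = FALSE]
    in_iap <- rep(FALSE, nrow(sites))
    if (nrow(iap)) {
      site_gr <- GenomicRanges::GRanges(sites$chrom,
        IRanges::IRanges(sites$pos + 1L, width = 1L))
      in_iap <- .overlaps_any(site_gr, .gr(iap))
    }
    m <- ifelse(in_iap, class_meth_mean(config, "IAP-like", day),
                class_meth_mean(config, "other", day))
    k <- config$beta_concentration
    rate <- numeric(nrow(sites))
    mid <- m > 0 & m < 1
    rate[mid] <- rbeta(sum(mid), m[mid] * k, (1 - m[mid]) * k)
    rate[m == 0] <- 0
    rate[m == 1] <- 1
    cov <- rpois(nrow(sites), config$coverage_mean)
    meth <- rbinom(nrow(sites), cov, rate)
    data.frame(chrom = sites$chrom, pos = sites$pos,
               count_meth = meth, count_unmeth = cov - meth,
               sample = sample)
  })
}
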