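#' Simulation configuration for the demethylation time-course generator
#'
#' Bundles every tunable parameter of the synthetic-data generator. The
#' defaults emulate an acute Dnmt1-deletion time course in mouse ESCs:
#' global CpG methylation collapsing from 85% to 35% (day 3) and 20%
#' (days 6/9) with IAP-like elements retaining +20 points; TE-class sense
#' activation coupled to methylation loss; genic TE insertions biased to
#' the antisense orientation (the "trap"); an AGO2-IP-like small RNA
#' library that is 90% miRNA with TE-derived 22-nt duplex siRNAs carrying
#' 2-nt 3' overhangs and a 5' U bias; and repressive-mark ChIP enrichment
#' that builds up late over specific TE classes.
#'
#' @param genome_length total genome size in bp, split evenly over
#'   `n_chroms` chromosomes.
#' @param n_chroms number of chromosomes.
#' @param n_genes number of non-overlapping genes.
#' @param n_te_instances TE instances per class.
#' @param te_classes character vector of TE class labels.
#' @param te_genic_fraction fraction of each class's instances placed
#'   inside gene bodies; the rest are intergenic, > 2 kb from any gene.
#' @param antisense_insertion_prob probability that a genic TE is
#'   oriented antisense to its host gene.
#' @param gene_length_range,te_length_range uniform length ranges (bp).
#' @param timepoints days of the time course.
#' @param meth_means named numeric: global mean methylation fraction per
#'   day (names = timepoints).
#' @param iap_meth_offset additive methylation offset for IAP-like TE
#'   CpGs, capped at 1.
#' @param te_activation numeric matrix class x timepoint of sense
#'   transcription multipliers.
#' @param basal_expression_floor lower bound on the (1 - methylation)
#'   coupling factor, i.e. leaky transcription of fully methylated TEs.
#' @param te_expr_scale overall weight of TE transcription relative to
#'   genic transcription.
#' @param meth_insensitive_classes classes whose transcription ignores
#'   the methylome (constant across the time course).
#' @param cpg_density CpG sites per bp (default 1/100).
#' @param coverage_mean Poisson mean of per-CpG bisulfite coverage.
#' @param beta_concentration concentration of the Beta distribution of
#'   per-site methylation rates around the class/global mean.
#' @param n_replicates replicates per group in the default comparison
#'   design (RNA-seq, small RNA, differential tests).
#' @param rnaseq_library_size reads per RNA-seq sample.
#' @param read_length RNA-seq read length (bp).
#' @param mapq_low_fraction fraction of reads drawn with MAPQ < 20.
#' @param antisense_background fraction of a gene's transcription emitted
#'   on the opposite strand irrespective of TEs (pervasive background).
#' @param smallrna_library_size reads per small RNA sample.
#' @param smallrna_mirna_fraction fraction of the library that is miRNA.
#' @param smallrna_rrna_fraction fraction that is rRNA background.
#' @param smallrna_te_fraction fraction that is TE-derived duplex siRNA
#'   at the final timepoint; earlier days are scaled down by the
#'   class-summed sense x antisense transcript product.
#' @param sirna_length_dist named numeric over 20..24 nt, summing to 1.
#' @param mirna_length_dist named numeric over miRNA lengths.
#' @param duplex_overhang 3' overhang of siRNA duplexes (nt).
#' @param five_prime_u_prob probability a siRNA guide starts with U.
#' @param n_mirna_loci,n_rrna_loci numbers of annotated miRNA/rRNA loci.
#' @param consensus_length length (bp) of each TE class consensus.
#' @param chip_library_size reads per ChIP sample.
#' @param tile_width ChIP tile width (bp).
#' @param chip_marks histone marks simulated.
#' @param chip_enrichment nested list `mark -> class -> numeric per
#'   timepoint` of Poisson-rate multipliers for tiles overlapping that
#'   class (missing entries default to 1).
#' @param seed root RNG seed; all samples/stages derive child streams
#'   deterministically from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 2e6,
                       n_chroms = 2,
                       n_genes = 200,
                       n_te_instances = 60,
                       te_classes = c("IAP-like", "MERVL-like", "ETn-like",
                                      "L1-like", "MMERVK-like",
                                      "neutral-SINE-like"),
                       te_genic_fraction = 0.10,
                       antisense_insertion_prob = 0.7,
                       gene_length_range = c(1500, 4000),
                       te_length_range = c(500, 1200),
                       timepoints = c(0, 3, 6, 9),
                       meth_means = c("0" = 0.85, "3" = 0.35,
                                      "6" = 0.20, "9" = 0.20),
                       iap_meth_offset = 0.20,
                       te_activation = NULL,
                       basal_expression_floor = 0.05,
                       te_expr_scale = 0.15,
                       meth_insensitive_classes = "neutral-SINE-like",
                       cpg_density = 0.01,
                       coverage_mean = 10,
                       beta_concentration = 20,
                       n_replicates = 3,
                       rnaseq_library_size = 1e5,
                       read_length = 100,
                       mapq_low_fraction = 0.05,
                       antisense_background = 0.06,
                       smallrna_library_size = 4e5,
                       smallrna_mirna_fraction = 0.90,
                       smallrna_rrna_fraction = 0.02,
                       smallrna_te_fraction = 0.032,
                       sirna_length_dist = c("20" = 0.05, "21" = 0.15,
                                             "22" = 0.55, "23" = 0.15,
                                             "24" = 0.10),
                       mirna_length_dist = c("21" = 0.25, "22" = 0.50,
                                             "23" = 0.25),
                       duplex_overhang = 2,
                       five_prime_u_prob = 0.75,
                       n_mirna_loci = 50,
                       n_rrna_loci = 5,
                       consensus_length = 1500,
                       chip_library_size = 2e5,
                       tile_width = 1000,
                       chip_marks = c("H3K27me3", "H3K9me3", "H3K9me2"),
                       chip_enrichment = NULL,
                       seed = 1) {
  if (is.null(te_activation)) {
    te_activation <- default_te_activation(te_classes, timepoints)
  }
  if (is.null(chip_enrichment)) {
    chip_enrichment <- default_chip_enrichment(chip_marks, te_classes,
                                               timepoints)
  }
  cfg <- structure(list(
    genome_length = genome_length, n_chroms = n_chroms, n_genes = n_genes,
    n_te_instances = n_te_instances, te_classes = te_classes,
    te_genic_fraction = te_genic_fraction,
    antisense_insertion_prob = antisense_insertion_prob,
    gene_length_range = gene_length_range,
    te_length_range = te_length_range,
    timepoints = timepoints, meth_means = meth_means,
    iap_meth_offset = iap_meth_offset, te_activation = te_activation,
    basal_expression_floor = basal_expression_floor,
    te_expr_scale = te_expr_scale,
    meth_insensitive_classes = meth_insensitive_classes,
    n_replicates = n_replicates,
    cpg_density = cpg_density, coverage_mean = coverage_mean,
    beta_concentration = beta_concentration,
    rnaseq_library_size = rnaseq_library_size, read_length = read_length,
    mapq_low_fraction = mapq_low_fraction,
    antisense_background = antisense_background,
    smallrna_library_size = smallrna_library_size,
    smallrna_mirna_fraction = smallrna_mirna_fraction,
    smallrna_rrna_fraction = smallrna_rrna_fraction,
    smallrna_te_fraction = smallrna_te_fraction,
    sirna_length_dist = sirna_length_dist,
    mirna_length_dist = mirna_length_dist,
    duplex_overhang = duplex_overhang,
    five_prime_u_prob = five_prime_u_prob,
    n_mirna_loci = n_mirna_loci, n_rrna_loci = n_rrna_loci,
    consensus_length = consensus_length,
    chip_library_size = chip_library_size, tile_width = tile_width,
    chip_marks = chip_marks, chip_enrichment = chip_enrichment,
    seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# Default sense-activation multipliers: ERV-type classes activate upon
# demethylation; IAP-like is partly resilenced by day 9; the neutral
# SINE-like class never responds (the negative control).
default_te_activation <- function(classes, timepoints) {
  base <- rbind(
    "IAP-like"          = c(1, 6, 10, 4),
    "MERVL-like"        = c(1, 4, 6, 6),
    "ETn-like"          = c(1, 3, 5, 5),
    "L1-like"           = c(1, 2, 4, 4),
    "MMERVK-like"       = c(1, 3, 5, 5),
    "neutral-SINE-like" = c(1, 1, 1, 1)
  )
  m <- matrix(1, length(classes), length(timepoints),
              dimnames = list(classes, as.character(timepoints)))
  common <- intersect(classes, rownames(base))
  k <- min(ncol(base), ncol(m))
  m[common, seq_len(k)] <- base[common, seq_len(k)]
  m
}

# Default repressive-mark enrichment: the chronic chromatin response
# builds up at late timepoints, strongest for IAP-like; H3K9me3 marks
# IAP-like constitutively.
default_chip_enrichment <- function(marks, classes, timepoints) {
  tp <- as.character(timepoints)
  one <- function(v) setNames(v[seq_along(tp)], tp)
  enr <- list(
    "H3K27me3" = list(
      "IAP-like" = one(c(1, 1, 1.8, 2.5)), "MERVL-like" = one(c(1, 1, 1.2, 1.5)),
      "ETn-like" = one(c(1, 1, 1.2, 1.5)), "L1-like" = one(c(1, 1, 1.1, 1.3)),
      "MMERVK-like" = one(c(1, 1, 1.2, 1.5))
    ),
    "H3K9me2" = list(
      "IAP-like" = one(c(1, 1, 1.5, 2.5)), "L1-like" = one(c(1, 1, 1.1, 1.2))
    ),
    "H3K9me3" = list("IAP-like" = one(rep(1.5, length(tp))))
  )
  enr[intersect(marks, names(enr))]
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: probabilities in `[0,1]`,
#' length-distribution masses summing to 1 (within 1e-9), positive sizes,
#' and methylation means defined for every timepoint.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly; errors describe the violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c(te_genic_fraction = cfg$te_genic_fraction,
             antisense_insertion_prob = cfg$antisense_insertion_prob,
             mapq_low_fraction = cfg$mapq_low_fraction,
             antisense_background = cfg$antisense_background,
             smallrna_mirna_fraction = cfg$smallrna_mirna_fraction,
             smallrna_rrna_fraction = cfg$smallrna_rrna_fraction,
             smallrna_te_fraction = cfg$smallrna_te_fraction,
             five_prime_u_prob = cfg$five_prime_u_prob)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities outside [0,1]: ",
         paste(names(probs)[bad], collapse = ", "))
  }
  if (any(cfg$meth_means < 0 | cfg$meth_means > 1)) {
    stop("meth_means must be fractions in [0,1]")
  }
  if (!all(as.character(cfg$timepoints) %in% names(cfg$meth_means))) {
    stop("meth_means must name every timepoint: ",
         paste(cfg$timepoints, collapse = ", "))
  }
  for (nm in c("sirna_length_dist", "mirna_length_dist")) {
    if (abs(sum(cfg[[nm]]) - 1) > 1e-9) {
      stop(nm, " masses must sum to 1 (got ", sum(cfg[[nm]]), ")")
    }
    if (any(cfg[[nm]] < 0)) stop(nm, " masses must be non-negative")
  }
  if (cfg$smallrna_mirna_fraction + cfg$smallrna_rrna_fraction +
      cfg$smallrna_te_fraction > 1) {
    stop("small RNA composition fractions exceed 1")
  }
  if (cfg$genome_length <= 0 || cfg$n_chroms < 1) {
    stop("genome_length and n_chroms must be positive")
  }
  if (!is.matrix(cfg$te_activation) ||
      !all(cfg$te_classes %in% rownames(cfg$te_activation))) {
    stop("te_activation must be a class x timepoint matrix covering te_classes")
  }
  if (cfg$duplex_overhang < 0) stop("duplex_overhang must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$genome_length, "bp /", x$n_chroms, "chromosomes,",
      x$n_genes, "genes,", x$n_te_instances, "TEs x",
      length(x$te_classes), "classes\n")
  cat("  timepoints (days):", paste(x$timepoints, collapse = ", "), "\n")
  cat("  global methylation:",
      paste(sprintf("d%s=%.0f%%", names(x$meth_means),
                    100 * x$meth_means), collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Mean methylation fraction for a class at a day (IAP-like offset, cap 1).
class_meth_mean <- function(cfg, class, day) {
  m <- unname(cfg$meth_means[[as.character(day)]])
  ifelse(class == "IAP-like", pmin(1, m + cfg$iap_meth_offset), m)
}

# Linear coupling of transcription to methylation loss, with basal
# floor; methylation-insensitive classes transcribe at a constant rate
# regardless of the methylome (the negative control).
expression_coupling <- function(cfg, class, day) {
  out <- pmax(1 - class_meth_mean(cfg, class, day),
              cfg$basal_expression_floor)
  out[class %in% cfg$meth_insensitive_classes] <- 1
  out
}

check_day <- function(cfg, day) {
  if (!day %in% cfg$timepoints) {
    stop("unknown day ", day, "; configured timepoints: ",
         paste(cfg$timepoints, collapse = ", "))
  }
}
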