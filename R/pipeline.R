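#' Run the simulate-then-quantify pipeline
#'
#' Executes the stages in dependency order — simulate, genic-exclusion
#' filter, TE-class expression, antisense trap statistic, methylome
#' windows, small RNA signature, ChIP enrichment — and writes every
#' intermediate file plus a combined machine-readable report and a run
#' manifest to `outdir`. The default design compares the first timepoint
#' (WT) against the last (KO): two RNA-seq and two small RNA replicates
#' per group, one methylome per timepoint, one ChIP sample per mark for
#' WT and KO.
#'
#' @param config a [sim_config()].
#' @param stages character subset of
#'   `c("simulate", "te_expression", "antisense", "methylome",
#'   "smallrna", "chip")`; dependencies are implied (every analysis
#'   stage needs `simulate`).
#' @param seed root seed; overrides `config$seed` when given.
#' @param outdir output directory (created).
#' @return a list with `report` (the combined analysis summaries),
#'   `manifest` (config echo, seed, per-stage outputs with MD5 hashes)
#'   and `annotation`; the same content is written to
#'   `report.json`/`manifest.json`.
#' @export
run_pipeline <- function(config = sim_config(),
                         stages = c("simulate", "te_expression",
                                    "antisense", "methylome", "smallrna",
                                    "chip"),
                         seed = NULL, outdir = tempfile("tetrap_run_")) {
  all_stages <- c("simulate", "te_expression", "antisense", "methylome",
                  "smallrna", "chip")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) config$seed <- seed
  validate_sim_config(config)
  if (!"simulate" %in% stages && length(setdiff(stages, "simulate"))) {
    stop("stage dependency not met: every analysis stage requires 'simulate'")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  d0 <- min(config$timepoints)
  d1 <- max(config$timepoints)
  report <- list()
  outputs <- character(0)
  log <- list()

  ann <- build_genome(config)
  if ("simulate" %in% stages) {
    write_gff3_genes(ann$genes, file.path(outdir, "genes.gff3"))
    write_te_bed(ann$tes, file.path(outdir, "tes.bed"))
    write_consensus_fasta(ann$consensus, file.path(outdir, "consensus.fa"))
    outputs <- c(outputs, "genes.gff3", "tes.bed", "consensus.fa")
  }

  tes_filtered <- filter_tes_near_genes(ann$tes, ann$genes)
  log$tes_removed_near_genes <- attr(tes_filtered, "n_removed")
  log$tes_retained <- nrow(tes_filtered)

  if ("te_expression" %in% stages || "antisense" %in% stages) {
    nrep <- config$n_replicates
    samples <- setNames(c(rep(d0, nrep), rep(d1, nrep)),
                        c(paste0("WT_", seq_len(nrep)),
                          paste0("KO_", seq_len(nrep))))
    reads <- lapply(names(samples), function(s) {
      simulate_rnaseq(ann, config, s, samples[[s]])
    })
    names(reads) <- names(samples)
    for (s in names(reads)) {
      write_reads(reads[[s]], file.path(outdir, paste0("rnaseq_", s, ".bed")))
    }
    outputs <- c(outputs, paste0("rnaseq_", names(reads), ".bed"))
    all_reads <- do.call(rbind, reads)
    libs <- setNames(rep(config$rnaseq_library_size, length(samples)),
                     names(samples))

    if ("te_expression" %in% stages) {
      cnt_s <- count_overlaps(all_reads, tes_filtered, orientation = "sense")
      cnt_a <- count_overlaps(all_reads, tes_filtered,
                              orientation = "antisense")
      log$rnaseq_mapq_discarded <- attr(cnt_s, "n_mapq_discarded")
      summ <- summarize_te_classes(rbind(cnt_s, cnt_a), tes_filtered)
      log$te_instances_dropped_low_count <- length(summ$dropped)
      rpm_s <- class_log2_rpm(summ, libs, "sense")
      rpm_a <- class_log2_rpm(summ, libs, "antisense")
      z <- zscore_by_class(rpm_s)
      diff <- differential_te(rpm_s, factor(sub("_.*", "", colnames(rpm_s)),
                                            levels = c("WT", "KO")))
      cls_tab <- summ$counts
      names(cls_tab)[names(cls_tab) == "class"] <- "feature"
      write_count_table(cls_tab, file.path(outdir, "te_class_counts.tsv"))
      outputs <- c(outputs, "te_class_counts.tsv")
      report$te_expression <- list(
        log2_rpm_sense = as.data.frame(rpm_s),
        log2_rpm_antisense = as.data.frame(rpm_a),
        zscores = as.data.frame(unclass(z)),
        differential = diff
      )
    }

    if ("antisense" %in% stages) {
      genes <- ann$genes
      per_sample <- lapply(reads, function(rd) {
        gene_orientation_counts(
          count_overlaps(rd, genes, orientation = "sense"),
          count_overlaps(rd, genes, orientation = "antisense"))
      })
      pool <- function(who) {
        gc <- per_sample[[who[1]]]
        for (w in who[-1]) {
          gc$sense <- gc$sense + per_sample[[w]]$sense
          gc$antisense <- gc$antisense + per_sample[[w]]$antisense
        }
        gc
      }
      wt_names <- grep("^WT_", names(samples), value = TRUE)
      ko_names <- grep("^KO_", names(samples), value = TRUE)
      wt_pool <- pool(wt_names); ko_pool <- pool(ko_names)
      p0 <- global_antisense_proportion(ko_pool)
      bin <- binomial_antisense_test(ko_pool, p0)
      log$antisense_zero_genes_excluded <- attr(bin, "n_zero_excluded")
      amat <- function(who) {
        m <- sapply(who, function(w) per_sample[[w]]$antisense)
        rownames(m) <- per_sample[[who[1]]]$gene
        m
      }
      diffa <- differential_antisense(amat(wt_names), amat(ko_names),
                                      libs[wt_names], libs[ko_names])
      aset <- antisense_gene_set(bin, diffa, wt_pool, ko_pool)
      report$antisense <- list(global_p0 = p0, genes = aset$genes,
                               n_binomial = aset$n_binomial,
                               n_differential = aset$n_differential,
                               summary = aset$summary)
    }
  }

  if ("methylome" %in% stages) {
    wins <- lapply(config$timepoints, function(d) {
      calls <- simulate_methylome(ann, config, paste0("meth_d", d), d)
      write_meth_coverage(calls, file.path(outdir,
                                           paste0("meth_d", d, ".cov")))
      window_methylation(calls)
    })
    names(wins) <- paste0("day", config$timepoints)
    outputs <- c(outputs, paste0("meth_d", config$timepoints, ".cov"))
    report$methylome <- list(
      mean_window_percent = vapply(wins, function(w) {
        mean(w$percent_methylation)
      }, 0),
      comparisons = compare_methylomes(wins)
    )
  }

  if ("smallrna" %in% stages) {
    sr <- simulate_smallrna(ann, config, "AGO2_KO", d1)
    sr20 <- filter_by_length(sr)
    log$smallrna_length_filtered <- attr(sr20, "n_removed")
    bins <- hierarchical_exclusion(sr20, ann$rrna, ann$mirna, ann$tes)
    te_reads <- assign_te_class(bins$repeat_assignable, ann$tes)
    te_reads <- te_reads[!is.na(te_reads$te_class), , drop = FALSE]
    sig <- overlap_signature(te_reads)
    comp <- five_prime_composition(te_reads)
    lsd <- length_strand_distribution(te_reads)
    n_nonmir <- nrow(sr20) - nrow(bins$miRNA) - nrow(bins$rRNA)
    report$smallrna <- list(
      pct_mirna = 100 * nrow(bins$miRNA) / nrow(sr20),
      pct_te_of_rest = if (n_nonmir > 0) 100 * nrow(te_reads) / n_nonmir else 0,
      length_mode = as.integer(names(which.max(rowSums(lsd)))),
      five_prime_u = unname(comp["U"]),
      overlap_mode = sig$mode,
      overlap_z_at_mode = if (!sig$empty)
        unname(sig$zscores[as.character(sig$mode)]) else NA_real_
    )
  }

  if ("chip" %in% stages) {
    enrich <- list(); flags <- list()
    for (mark in config$chip_marks) {
      te_wt <- tile_log2_obs_exp(simulate_chip(ann, config, "WT", mark, d0))
      te_ko <- tile_log2_obs_exp(simulate_chip(ann, config, "KO", mark, d1))
      write_tile_counts(te_ko, file.path(outdir,
                                         paste0("chip_", mark, "_KO.tsv")))
      res <- te_class_chip_enrichment(list(WT = te_wt, KO = te_ko),
                                      tes_filtered, ko = "KO", wt = "WT")
      enrich[[mark]] <- as.data.frame(res$log2_oe)
      flags[[mark]] <- names(res$flagged)[res$flagged]
    }
    outputs <- c(outputs, paste0("chip_", config$chip_marks, "_KO.tsv"))
    report$chip <- list(log2_oe = enrich, flagged = flags)
  }

  report$filter_log <- log
  manifest <- list(
    seed = config$seed,
    stages = stages,
    outputs = outputs,
    md5 = as.list(setNames(unname(tools::md5sum(file.path(outdir, outputs))),
                           outputs)),
    parameters = config[c("genome_length", "n_genes", "n_te_instances",
                          "timepoints", "rnaseq_library_size",
                          "smallrna_library_size", "chip_library_size")]
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  list(report = report, manifest = manifest, annotation = ann,
       outdir = outdir)
}
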