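#' Build a synthetic genome annotation
#'
#' Lays out non-overlapping genes and TE instances on a small multi-
#' chromosome genome. A configurable fraction of each TE class's
#' instances is placed inside gene bodies (at most one TE per host gene),
#' oriented antisense to the host with probability
#' `antisense_insertion_prob` — the "trap" configuration. All remaining
#' instances are intergenic and kept strictly more than 2 kb away from
#' every gene so they survive the genic-exclusion filter downstream.
#' miRNA and rRNA loci (for the small RNA exclusion hierarchy) and one
#' random consensus sequence per TE class are generated alongside.
#'
#' @param config a [sim_config()].
#' @return an object of class `genome_annotation`: a list with
#'   `chrom_sizes` (named integer), `genes`, `tes`, `mirna`, `rrna`
#'   (data frames in 0-based half-open coordinates), `consensus`
#'   (a [Biostrings::DNAStringSet], one per TE class) and `config`.
#'   `tes` carries `class`, `host_gene` (NA if intergenic) and a
#'   simulation-truth base expression weight.
#' @export
build_genome <- function(config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "genome"), build_genome_impl(config))
}

build_genome_impl <- function(cfg) {
  chrom_size <- floor(cfg$genome_length / cfg$n_chroms)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- setNames(rep(chrom_size, cfg$n_chroms), chroms)
  margin <- 2000L

  n_classes <- length(cfg$te_classes)
  n_genic_per_class <- round(cfg$te_genic_fraction * cfg$n_te_instances)
  n_inter_per_class <- cfg$n_te_instances - n_genic_per_class

  te_len <- function(n) {
    as.integer(round(runif(n, cfg$te_length_range[1], cfg$te_length_range[2])))
  }

  genes_per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  inter_tes <- data.frame(class = rep(cfg$te_classes, each = n_inter_per_class))
  inter_tes$length <- te_len(nrow(inter_tes))
  inter_tes$chrom_idx <- sample(rep(seq_len(cfg$n_chroms),
                                    length.out = nrow(inter_tes)))

  genes <- list(); tes <- list()
  gene_id0 <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    ng <- genes_per_chrom[ci]
    glen <- as.integer(round(runif(ng, cfg$gene_length_range[1],
                                   cfg$gene_length_range[2])))
    my_tes <- inter_tes[inter_tes$chrom_idx == ci, , drop = FALSE]

    # Assign each intergenic TE to one of the ng+1 gaps between genes;
    # a gap adjacent to a gene needs > `margin` clearance on that side.
    gap_of <- sample.int(ng + 1, nrow(my_tes), replace = TRUE)
    gap_need <- integer(ng + 1)
    for (g in seq_len(ng + 1)) {
      in_gap <- which(gap_of == g)
      left_margin <- if (g > 1) margin + 1L else 0L
      right_margin <- if (g <= ng) margin + 1L else 0L
      gap_need[g] <- left_margin + right_margin +
        sum(my_tes$length[in_gap]) + 20L * length(in_gap)
    }
    need <- sum(glen) + sum(gap_need)
    if (need > chrom_size) {
      stop("genome too small to place requested features on ", chroms[ci],
           ": need >= ", need, " bp (genes + TEs + 2 kb gene margins) but ",
           "chromosome is ", chrom_size, " bp")
    }
    # Spread the slack over the gaps.
    slack <- chrom_size - need
    extra <- as.vector(rmultinom(1, slack, rep(1, ng + 1)))

    pos <- 0L
    for (g in seq_len(ng + 1)) {
      in_gap <- which(gap_of == g)
      pos <- pos + (if (g > 1) margin + 1L else 0L)
      # half the gap slack before the TEs, half after
      pos <- pos + extra[g] %/% 2L
      for (i in in_gap) {
        start <- pos + sample.int(20L, 1L)
        tes[[length(tes) + 1L]] <- data.frame(
          chrom = chroms[ci], start = start,
          end = start + my_tes$length[i],
          strand = sample(c("+", "-"), 1L),
          class = my_tes$class[i], host_gene = NA_character_
        )
        pos <- start + my_tes$length[i]
      }
      pos <- pos + (extra[g] - extra[g] %/% 2L) +
        (if (g <= ng) margin + 1L else 0L)
      if (g <= ng) {
        gene_id0 <- gene_id0 + 1L
        genes[[length(genes) + 1L]] <- data.frame(
          chrom = chroms[ci], start = pos, end = pos + glen[g],
          strand = sample(c("+", "-"), 1L),
          id = sprintf("gene%03d", gene_id0)
        )
        pos <- pos + glen[g]
      }
    }
  }
  genes <- do.call(rbind, genes)
  tes <- do.call(rbind, tes)

  # Genic TEs: distinct host genes, TE fully inside the gene body,
  # antisense to the host with the configured probability.
  n_genic <- n_genic_per_class * n_classes
  if (n_genic > 0) {
    glen_all <- genes$end - genes$start
    need_len <- max(cfg$te_length_range) + 40L
    eligible <- which(glen_all >= need_len)
    if (length(eligible) < n_genic) {
      stop("genome too small to place requested features: only ",
           length(eligible), " genes can host a TE but ", n_genic,
           " genic insertions requested")
    }
    hosts <- sample(eligible, n_genic)
    gcls <- rep(cfg$te_classes, each = n_genic_per_class)
    glen_te <- te_len(n_genic)
    off <- floor(runif(n_genic) *
                   (glen_all[hosts] - glen_te - 20L)) + 10L
    anti <- runif(n_genic) < cfg$antisense_insertion_prob
    host_strand <- genes$strand[hosts]
    strand <- ifelse(anti, ifelse(host_strand == "+", "-", "+"), host_strand)
    genic <- data.frame(
      chrom = genes$chrom[hosts], start = genes$start[hosts] + off,
      end = genes$start[hosts] + off + glen_te, strand = strand,
      class = gcls, host_gene = genes$id[hosts]
    )
    tes <- rbind(tes, genic)
  }
  tes <- tes[order(tes$chrom, tes$start), ]
  rownames(tes) <- NULL
  tes$id <- sprintf("te%04d", seq_len(nrow(tes)))
  tes$base_expr <- rlnorm(nrow(tes), 0, 0.3)
  genes$base_expr <- rlnorm(nrow(genes), 0, 0.3)

  # miRNA / rRNA loci in gene-free, TE-free space: reuse small slots
  # sampled uniformly with rejection.
  aux <- place_aux_loci(cfg, chroms, chrom_sizes, genes, tes)

  consensus <- random_consensus(cfg)

  structure(list(chrom_sizes = chrom_sizes, genes = genes, tes = tes,
                 mirna = aux$mirna, rrna = aux$rrna,
                 consensus = consensus, config = cfg),
            class = "genome_annotation")
}

place_aux_loci <- function(cfg, chroms, chrom_sizes, genes, tes) {
  occupied <- rbind(genes[c("chrom", "start", "end")],
                    tes[c("chrom", "start", "end")])
  occ_gr <- .gr(occupied)
  draw <- function(n, len, prefix) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      id = character(0))
    tries <- 0L
    while (nrow(out) < n && tries < 200L) {
      tries <- tries + 1L
      m <- n - nrow(out)
      chrom <- sample(chroms, m, replace = TRUE)
      start <- floor(runif(m) * (chrom_sizes[chrom] - len))
      cand <- data.frame(chrom = chrom, start = as.integer(start),
                         end = as.integer(start + len),
                         strand = sample(c("+", "-"), m, replace = TRUE))
      hit <- .overlaps_any(.gr(cand), occ_gr)
      if (nrow(out) > 0) {
        hit <- hit | .overlaps_any(.gr(cand), .gr(out))
      }
      cand <- cand[!hit, , drop = FALSE]
      if (nrow(cand)) {
        cand$id <- sprintf("%s%03d", prefix,
                           nrow(out) + seq_len(nrow(cand)))
        out <- rbind(out, cand)
      }
    }
    if (nrow(out) < n) {
      stop("genome too small to place requested features: could not place ",
           n, " ", prefix, " loci outside genes/TEs")
    }
    out$sequence <- random_seq(nrow(out), len)
    out
  }
  list(mirna = draw(cfg$n_mirna_loci, 80L, "mir"),
       rrna = draw(cfg$n_rrna_loci, 150L, "rrna"))
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

random_consensus <- function(cfg) {
  seqs <- random_seq(length(cfg$te_classes), cfg$consensus_length)
  Biostrings::DNAStringSet(setNames(seqs, cfg$te_classes))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", sum(x$chrom_sizes), "bp over",
      length(x$chrom_sizes), "chromosomes\n")
  cat(" ", nrow(x$genes), "genes;", nrow(x$tes), "TE instances (",
      sum(!is.na(x$tes$host_gene)), "genic );",
      nrow(x$mirna), "miRNA and", nrow(x$rrna), "rRNA loci\n")
  cat("  TE classes:", paste(unique(x$tes$class), collapse = ", "), "\n")
  invisible(x)
}
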