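#' Simulate an AGO2-IP-like small RNA library
#'
#' The library mixes (i) miRNA reads from the annotated miRNA loci
#' (`smallrna_mirna_fraction` of the library), (ii) an rRNA background,
#' (iii) TE-derived duplex siRNAs and (iv) unannotated genomic reads.
#' Each siRNA duplex places a sense guide of length L1 at consensus/
#' genomic position s and an antisense guide of length L2 starting at
#' `s - duplex_overhang`, so the antisense guide's 3' end overhangs the
#' sense 5' end by `duplex_overhang` nt and the 5'-5' overlap is
#' `L2 - duplex_overhang` (mode 22 - 2 = 20 under the default length
#' distribution). Guide 5' bases are U with probability
#' `five_prime_u_prob`. Per-class duplex abundance scales with the
#' class's sense x antisense transcript product at that day, and the
#' total TE fraction reaches `smallrna_te_fraction` at the final
#' timepoint.
#'
#' @inheritParams simulate_methylome
#' @return a data frame of small RNA reads: `chrom`, `start`, `end`,
#'   `strand`, `length`, `sequence` (DNA alphabet, T for U), `sample`,
#'   `consensus`/`cpos` (TE class consensus and 0-based offset, NA for
#'   non-TE reads) and the truth label `source_type`
#'   (`miRNA`, `rRNA`, `other`, or `TE:<class>`).
#' @export
simulate_smallrna <- function(annotation, config = annotation$config,
                              sample, day) {
  check_day(config, day)
  with_seed(child_seed(config$seed, "smallrna", sample, day), {
    lib <- config$smallrna_library_size
    n_mirna <- round(lib * config$smallrna_mirna_fraction)
    n_rrna <- round(lib * config$smallrna_rrna_fraction)
    w_cls <- sirna_class_weights(annotation, config, day)
    ref <- w_cls$total[[as.character(max(config$timepoints))]]
    scale_day <- if (ref > 0) w_cls$total[[as.character(day)]] / ref else 0
    n_te <- 2L * floor(lib * config$smallrna_te_fraction * scale_day / 2)
    n_other <- lib - n_mirna - n_rrna - n_te

    mirna <- sample_locus_reads(annotation$mirna, n_mirna,
                                config$mirna_length_dist, "miRNA")
    rrna <- sample_locus_reads(annotation$rrna, n_rrna,
                               config$sirna_length_dist, "rRNA")
    other <- sample_other_reads(annotation, n_other, config)
    sirna <- sample_sirna_duplexes(annotation, config, day, n_te / 2,
                                   w_cls$class_w)
    out <- rbind(mirna, rrna, other, sirna)
    out$sample <- sample
    rownames(out) <- NULL
    out
  })
}

# Class-level siRNA weights: sense rate x antisense rate proxies. The
# sense rate is activation x coupling; the antisense rate is carried by
# host-gene transcription over antisense-inserted instances, so classes
# without antisense genic copies produce no siRNA.
sirna_class_weights <- function(annotation, cfg, day) {
  tes <- annotation$tes
  genes <- annotation$genes
  gene_expr <- setNames(genes$base_expr, genes$id)
  per_day <- sapply(as.character(cfg$timepoints), function(d) {
    sapply(cfg$te_classes, function(cl) {
      inst <- tes[tes$class == cl & !is.na(tes$host_gene), , drop = FALSE]
      if (!nrow(inst)) return(0)
      anti <- inst$strand != genes$strand[match(inst$host_gene, genes$id)]
      sense_rate <- cfg$te_activation[cl, d] *
        expression_coupling(cfg, cl, as.numeric(d))
      sum(sense_rate * inst$base_expr[anti] *
            gene_expr[inst$host_gene[anti]])
    })
  })
  w <- per_day[, as.character(day)]
  list(class_w = w, total = colSums(per_day))
}

sample_locus_reads <- function(loci, n, length_dist, label) {
  if (n == 0 || nrow(loci) == 0) return(empty_smallrna())
  li <- sample.int(nrow(loci), n, replace = TRUE)
  len <- sample_vals(as.integer(names(length_dist)), n, length_dist)
  off <- floor(runif(n) * (loci$end[li] - loci$start[li] - len))
  seqs <- substring(loci$sequence[li], off + 1L, off + len)
  minus <- loci$strand[li] == "-"
  seqs[minus] <- revcomp(seqs[minus])
  data.frame(chrom = loci$chrom[li],
             start = as.integer(loci$start[li] + off),
             end = as.integer(loci$start[li] + off + len),
             strand = loci$strand[li], length = len, sequence = seqs,
             consensus = NA_character_, cpos = NA_integer_,
             source_type = label)
}

# Unannotated genomic reads: uniform positions rejected against TE,
# miRNA and rRNA annotation so they land in the non-repeat genome bin.
sample_other_reads <- function(annotation, n, cfg) {
  if (n == 0) return(empty_smallrna())
  chroms <- names(annotation$chrom_sizes)
  occ <- .gr(rbind(annotation$tes[c("chrom", "start", "end")],
                   annotation$mirna[c("chrom", "start", "end")],
                   annotation$rrna[c("chrom", "start", "end")]))
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    m <- n - if (is.null(out)) 0L else nrow(out)
    len <- sample_vals(as.integer(names(cfg$sirna_length_dist)), m,
                       cfg$sirna_length_dist)
    chrom <- sample(chroms, m, replace = TRUE)
    start <- floor(runif(m) * (annotation$chrom_sizes[chrom] - len))
    cand <- data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(start + len),
                       strand = sample(c("+", "-"), m, replace = TRUE),
                       length = len)
    keep <- !.overlaps_any(.gr(cand), occ)
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand)) {
      cand$sequence <- random_kmer(nrow(cand), cand$length)
      cand$consensus <- NA_character_
      cand$cpos <- NA_integer_
      cand$source_type <- "other"
      out <- rbind(out, cand)
    }
  }
  out
}

sample_sirna_duplexes <- function(annotation, cfg, day, n_duplex, class_w) {
  if (n_duplex == 0 || sum(class_w) == 0) return(empty_smallrna())
  tes <- annotation$tes
  genes <- annotation$genes
  cons <- as.character(annotation$consensus)
  oh <- as.integer(cfg$duplex_overhang)
  lens <- as.integer(names(cfg$sirna_length_dist))

  cls <- sample(names(class_w), n_duplex, replace = TRUE, prob = class_w)
  # duplexes arise at antisense genic instances (where the dsRNA forms)
  anti_genic <- tes[!is.na(tes$host_gene) &
                      tes$strand != genes$strand[match(tes$host_gene,
                                                       genes$id)], ,
                    drop = FALSE]
  rows <- lapply(split(seq_len(n_duplex), cls), function(ix) {
    cl <- cls[ix[1]]
    inst <- anti_genic[anti_genic$class == cl, , drop = FALSE]
    if (!nrow(inst)) return(NULL)
    k <- length(ix)
    ii <- sample.int(nrow(inst), k, replace = TRUE,
                     prob = inst$base_expr)
    L1 <- sample_vals(lens, k, cfg$sirna_length_dist)
    L2 <- sample_vals(lens, k, cfg$sirna_length_dist)
    ilen <- inst$end[ii] - inst$start[ii]
    # consensus space: sense guide [cs, cs+L1), antisense guide
    # [cs-oh, cs-oh+L2), both inside the instance; the 5'-5' overlap is
    # L2 - oh whichever genome strand the instance is on
    lo <- oh
    hi <- pmin(ilen - L1, ilen - L2 + oh)
    cs <- lo + floor(runif(k) * pmax(hi - lo, 1L))
    sense_seq <- substring(cons[cl], cs + 1L, cs + L1)
    anti_seq <- revcomp(substring(cons[cl], cs - oh + 1L, cs - oh + L2))
    sense_seq <- apply_5p_u(sense_seq, cfg$five_prime_u_prob)
    anti_seq <- apply_5p_u(anti_seq, cfg$five_prime_u_prob)
    plus_te <- inst$strand[ii] == "+"
    # genomic mapping: plus instances run with the consensus, minus
    # instances reverse it
    sen_start <- ifelse(plus_te, inst$start[ii] + cs,
                        inst$end[ii] - cs - L1)
    ant_start <- ifelse(plus_te, inst$start[ii] + cs - oh,
                        inst$end[ii] - (cs - oh) - L2)
    rbind(
      data.frame(chrom = inst$chrom[ii], start = as.integer(sen_start),
                 end = as.integer(sen_start + L1),
                 strand = ifelse(plus_te, "+", "-"), length = L1,
                 sequence = sense_seq, consensus = cl,
                 cpos = as.integer(cs),
                 source_type = paste0("TE:", cl)),
      data.frame(chrom = inst$chrom[ii], start = as.integer(ant_start),
                 end = as.integer(ant_start + L2),
                 strand = ifelse(plus_te, "-", "+"), length = L2,
                 sequence = anti_seq, consensus = cl,
                 cpos = as.integer(cs - oh),
                 source_type = paste0("TE:", cl))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# sample() with a length-1 x would sample from 1:x; always index.
sample_vals <- function(vals, n, prob = NULL) {
  vals[sample.int(length(vals), n, replace = TRUE, prob = prob)]
}

empty_smallrna <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), length = integer(0),
             sequence = character(0), consensus = character(0),
             cpos = integer(0), source_type = character(0))
}

random_kmer <- function(n, lens) {
  maxlen <- max(lens)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * maxlen, replace = TRUE),
                nrow = n)
  full <- apply(mat, 1, paste, collapse = "")
  substring(full, 1L, lens)
}

# Force the 5' base to U (T internally) with probability p; otherwise
# draw uniformly from {A,C,G} so the U fraction is exactly p.
apply_5p_u <- function(seqs, p) {
  n <- length(seqs)
  if (!n) return(seqs)
  u <- runif(n) < p
  first <- ifelse(u, "T", sample(c("A", "C", "G"), n, replace = TRUE))
  paste0(first, substring(seqs, 2L))
}

revcomp <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
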