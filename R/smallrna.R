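#' Filter small RNA reads by length
#'
#' @param reads small RNA read data frame with a `length` column.
#' @param min_nt,max_nt inclusive bounds (defaults 20 and 24).
#' @return the retained reads, order preserved, with attribute
#'   `n_removed`.
#' @export
filter_by_length <- function(reads, min_nt = 20, max_nt = 24) {
  if (min_nt > max_nt) stop("min_nt must be <= max_nt")
  keep <- reads$length >= min_nt & reads$length <= max_nt
  structure(reads[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Hierarchical exclusion of small RNA reads
#'
#' Ordered partition with first-matching-rule-wins precedence:
#' (1) reads overlapping rRNA loci, (2) reads overlapping miRNA loci,
#' (3) reads mapping to the non-repeat genome (no overlap with any
#' masked/repeat region), (4) the remainder — reads over repeats,
#' available for TE-class assignment. Every read lands in exactly one
#' bin.
#'
#' @param reads small RNA read data frame (`chrom`, `start`, `end`).
#' @param rrna,mirna,repeats annotation data frames on the same
#'   coordinates (`repeats` is typically the TE annotation).
#' @return a named list of data frames `rRNA`, `miRNA`, `genome`,
#'   `repeat_assignable`; bin sizes sum to the input size.
#' @export
hierarchical_exclusion <- function(reads, rrna, mirna, repeats) {
  n <- nrow(reads)
  ov <- function(annot) {
    if (is.null(annot) || nrow(annot) == 0 || n == 0) return(rep(FALSE, n))
    .overlaps_any(.gr(reads), .gr(annot))
  }
  is_rrna <- ov(rrna)
  is_mirna <- !is_rrna & ov(mirna)
  in_repeat <- ov(repeats)
  is_genome <- !is_rrna & !is_mirna & !in_repeat
  rest <- !is_rrna & !is_mirna & !is_genome
  list(rRNA = reads[is_rrna, , drop = FALSE],
       miRNA = reads[is_mirna, , drop = FALSE],
       genome = reads[is_genome, , drop = FALSE],
       repeat_assignable = reads[rest, , drop = FALSE])
}

#' Assign repeat-borne reads to TE classes
#'
#' @param reads reads (typically the `repeat_assignable` bin).
#' @param tes TE annotation with `class`.
#' @return `reads` with a `te_class` column (NA when no overlap; ties
#'   resolved to the first overlapping instance).
#' @export
assign_te_class <- function(reads, tes) {
  reads$te_class <- NA_character_
  if (nrow(reads) && nrow(tes)) {
    hits <- .find_overlaps(.gr(reads), .gr(tes), select = "first")
    reads$te_class <- tes$class[hits]
  }
  reads
}

#' Length x strand distribution of small RNA reads
#'
#' @param reads read data frame with `length` and `strand`.
#' @return a table of counts, lengths x strand; its total equals the
#'   input size and its strand margin is the plain length histogram.
#' @export
length_strand_distribution <- function(reads) {
  table(length = reads$length, strand = reads$strand)
}

#' 5' nucleotide composition
#'
#' Fractions of A/C/G/U at read position 1 (U reported for T).
#'
#' @param reads read data frame with non-empty `sequence`.
#' @return named numeric over `A`, `C`, `G`, `U`, summing to 1.
#' @export
five_prime_composition <- function(reads) {
  if (nrow(reads) == 0) stop("empty read set")
  first <- toupper(substring(reads$sequence, 1L, 1L))
  first[first == "T"] <- "U"
  tab <- table(factor(first, levels = c("A", "C", "G", "U")))
  as.numeric(tab) / sum(tab) -> frac
  setNames(frac, c("A", "C", "G", "U"))
}

#' 5'-to-5' overlap signature of opposite-strand small RNAs
#'
#' For every plus-strand read (5' end at its start `s`) and minus-strand
#' read (5' end at its `end - 1`) on the same chromosome whose intervals
#' intersect, the overlap is `o = (minus 5' end) - s + 1`; counts are
#' aggregated over all qualifying pairs for `1 <= o <= max_overlap`.
#' Each overlap length's z-score is computed against the mean/SD of the
#' counts at all other lengths; the mode is the argmax. siRNA duplexes
#' with 2-nt 3' overhangs peak at (guide length - 2), i.e. 20 nt for
#' 22-nt guides.
#'
#' @param reads small RNA read data frame (`chrom`, `start`, `end`,
#'   `strand`).
#' @param max_overlap largest overlap length tabulated (default 30).
#' @return a list of class `overlap_signature`: `counts` (named over
#'   1..max_overlap), `zscores`, `mode` (NA when no opposite-strand pair
#'   exists, flagged by `empty`).
#' @export
overlap_signature <- function(reads, max_overlap = 30) {
  plus <- reads[reads$strand == "+", , drop = FALSE]
  minus <- reads[reads$strand == "-", , drop = FALSE]
  counts <- setNames(rep(0, max_overlap), seq_len(max_overlap))
  if (nrow(plus) && nrow(minus)) {
    hits <- .find_overlaps(.gr(plus), .gr(minus))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    o <- (minus$end[sh] - 1L) - plus$start[qh] + 1L
    o <- o[o >= 1 & o <= max_overlap]
    if (length(o)) {
      tab <- table(factor(o, levels = seq_len(max_overlap)))
      counts <- setNames(as.numeric(tab), seq_len(max_overlap))
    }
  }
  empty <- sum(counts) == 0
  z <- vapply(seq_len(max_overlap), function(i) {
    others <- counts[-i]
    s <- sd(others)
    if (is.na(s) || s == 0) return(NA_real_)
    (counts[i] - mean(others)) / s
  }, 0)
  structure(list(counts = counts,
                 zscores = setNames(z, seq_len(max_overlap)),
                 mode = if (empty) NA_integer_ else
                   as.integer(names(counts)[which.max(counts)]),
                 empty = empty),
            class = "overlap_signature")
}

#' @export
print.overlap_signature <- function(x, ...) {
  if (x$empty) {
    cat("overlap_signature: empty (no opposite-strand pairs)\n")
  } else {
    cat("overlap_signature: mode", x$mode, "nt (z =",
        round(x$zscores[as.character(x$mode)], 2), "),",
        sum(x$counts), "pairs\n")
  }
  invisible(x)
}

#' Per-position coverage over a consensus sequence
#'
#' @param reads reads mapped to one consensus, with `cpos` (0-based
#'   offset) and `length`.
#' @param consensus_length length of the consensus (bp).
#' @return integer coverage vector of length `consensus_length`; its sum
#'   equals the summed read lengths.
#' @export
consensus_profile <- function(reads, consensus_length) {
  if (nrow(reads)) {
    if (any(reads$cpos < 0 | reads$cpos + reads$length > consensus_length)) {
      stop("read outside consensus bounds [0, ", consensus_length, ")")
    }
  }
  cov <- integer(consensus_length)
  for (i in seq_len(nrow(reads))) {
    idx <- (reads$cpos[i] + 1L):(reads$cpos[i] + reads$length[i])
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

#' Locate reads on a consensus by exact substring matching
#'
#' For reads lacking consensus coordinates: exact occurrence of the read
#' sequence (plus strand) or its reverse complement (minus strand) in
#' the consensus, via Biostrings matching. Reads without a unique exact
#' match get NA.
#'
#' @param sequences character vector of read sequences.
#' @param consensus a single consensus sequence (character or
#'   `DNAString`).
#' @return integer vector of 0-based offsets (NA if no unique match).
#' @export
match_to_consensus <- function(sequences, consensus) {
  cons <- Biostrings::DNAString(as.character(consensus))
  vapply(sequences, function(s) {
    hits <- Biostrings::matchPattern(s, cons)
    if (length(hits) != 1) {
      hits <- Biostrings::matchPattern(as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s))), cons)
    }
    if (length(hits) == 1) Biostrings::start(hits)[1] - 1L else NA_integer_
  }, 0L, USE.NAMES = FALSE)
}

#' TE-class small RNA abundance and group comparison
#'
#' Per class, reads-per-million of the filtered library, compared
#' between two groups of replicate samples by a two-tailed Student's
#' t-test, with significance tiers `*` (p < 0.05) and `**` (p < 0.005).
#'
#' @param reads TE-assigned reads (with `te_class` and `sample`).
#' @param library_sizes named numeric: filtered-library size per sample.
#' @param groups named character/factor assigning each sample to one of
#'   two groups (first level = reference, e.g. day 0).
#' @return a list with `rpm` (classes x samples matrix) and `tests`
#'   (data frame `class`, `t`, `p`, `tier`).
#' @export
te_class_smallrna <- function(reads, library_sizes, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2 || min(table(groups)) < 2) {
    stop("need two groups with >= 2 replicates each")
  }
  samples <- names(library_sizes)
  classes <- sort(unique(stats::na.omit(reads$te_class)))
  rpm <- matrix(0, length(classes), length(samples),
                dimnames = list(classes, samples))
  tab <- table(factor(reads$te_class, levels = classes),
               factor(reads$sample, levels = samples))
  rpm[] <- sweep(unclass(tab), 2, library_sizes[samples] / 1e6, "/")
  g1 <- names(groups)[groups == levels(groups)[1]]
  g2 <- names(groups)[groups == levels(groups)[2]]
  tests <- do.call(rbind, lapply(classes, function(cl) {
    x <- rpm[cl, g2]; y <- rpm[cl, g1]
    if (sd(x) == 0 && sd(y) == 0) {
      data.frame(class = cl, t = 0, p = 1)
    } else {
      tt <- t.test(x, y, var.equal = TRUE)
      data.frame(class = cl, t = unname(tt$statistic), p = tt$p.value)
    }
  }))
  tests$tier <- ifelse(tests$p < 0.005, "**",
                       ifelse(tests$p < 0.05, "*", ""))
  list(rpm = rpm, tests = tests)
}
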