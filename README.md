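# tetrap

Analysis toolkit for transposable-element (TE) activation and its
silencing correlates during induced global DNA demethylation — the
regime of acute *Dnmt1* conditional knockout (cKO) in mouse embryonic
stem cells, and of epigenetic reprogramming in the early embryo and
germline. When methylation is erased, specific TE classes (IAP, ETn,
MERVL, MMERVK, LINE-1) transcribe; many TE copies sit antisense inside
transcribed genes, so TE activation produces sense/antisense read pairs
— a transcriptional "trap" that yields double-stranded RNA, DICER
processing, and AGO2-loaded endogenous siRNAs, followed later by
redistribution of repressive histone marks.

The package is aimed at epigenomics analysts who want the complete
quantification stack for this biology as reusable, tested functions:

* **TE-class expression** — strand-aware read/instance overlap counts
  (MAPQ ≥ 20, TEs within ±2 kb of genes excluded, instance counts > 3
  retained), class-summed and normalised to
  `log2RPM = log2( count / (library/10^6) / (class_length/10^3) + 1 )`,
  with per-class Z-scores across samples and Welch-*t*/Benjamini–
  Hochberg differential calls.
* **Pervasive antisense ("trap") statistic** — per gene, the one-sided
  exact binomial test
  `p = P(X ≥ antisense | n = sense + antisense, p0)` with `p0` the
  global antisense proportion `Σ antisense / Σ total`, BH-corrected;
  intersected with a replicate-aware differential antisense test to
  define the trap gene set.
* **Methylome quantitation** — call-weighted percent methylation in
  consecutive windows of 50 CpGs with coverage ≥ 3, CpG-weighted
  feature-level methylation (features with ≥ 50 qualifying CpGs),
  TE-class methylation with the ≥ 1000-observations-in-every-sample
  rule, and Wilcoxon rank-sum comparisons with Bonferroni correction.
* **endosiRNA signature** — 20–24 nt length filtering, hierarchical
  rRNA → miRNA → masked-genome exclusion, length × strand
  distributions, 5′ nucleotide composition, per-position consensus
  coverage, and the 5′–5′ overlap signature: for every intersecting
  plus/minus read pair, `o = (minus 5′ end) − (plus 5′ end) + 1`,
  tabulated over 1..30 with a z-score of each length against all
  others. siRNA duplexes with 2-nt 3′ overhangs peak at
  guide length − 2 = 20 nt.
* **Chromatin enrichment** — 1-kb genome tiles scored as
  `log2((observed + 1)/(expected + 1))` with the expected count from a
  uniform genome-wide distribution, TE-class means, Z-scores, and the
  ≥ 2-fold KO/WT enrichment flag.
* **Synthetic-data generator** — a calibrated simulator of the whole
  study (genome annotation, WT→cKO methylomes at 85 %/35 %/20 %,
  stranded RNA-seq with antisense TE insertions, AGO2-IP-like small RNA
  libraries that are 90 % miRNA with 22-nt 5′-U duplex siRNAs, ChIP
  tile counts) so every stage is verifiable at desk scale with no
  external data.

## Worked example

```r
library(tetrap)

cfg <- sim_config(seed = 1)      # the defaults are the study conditions
ann <- build_genome(cfg)
ann
#> genome_annotation: 2e+06 bp over 2 chromosomes
#>   200 genes; 360 TE instances ( 36 genic ); 50 miRNA and 5 rRNA loci
#>   TE classes: L1-like, IAP-like, MERVL-like, MMERVK-like, neutral-SINE-like, ETn-like

## methylome: wild type vs day 6 after deletion
w0 <- window_methylation(simulate_methylome(ann, cfg, "wgbs_d0", day = 0))
w6 <- window_methylation(simulate_methylome(ann, cfg, "wgbs_d6", day = 6))
sprintf("day 0: %.1f%%  day 6: %.1f%%",
        mean(w0$percent_methylation), mean(w6$percent_methylation))
#> "day 0: 85.4%  day 6: 20.6%"
compare_methylomes(list(day0 = w0, day6 = w6))
#>      a    b statistic       p_value  p_bonferroni significant
#> 1 day0 day6    158404 1.098468e-131 1.098468e-131        TRUE

## AGO2-IP-like small RNA library at day 9
sr <- filter_by_length(simulate_smallrna(ann, cfg, "AGO2_IP", day = 9))
bins <- hierarchical_exclusion(sr, ann$rrna, ann$mirna, ann$tes)
te <- assign_te_class(bins$repeat_assignable, ann$tes)
te <- te[!is.na(te$te_class), ]
overlap_signature(te)
#> overlap_signature: mode 20 nt (z = 13.26 ), 73518 pairs
round(five_prime_composition(te), 3)
#>     A     C     G     U
#> 0.082 0.081 0.084 0.753
```

The methylome recovers the configured 85 % → 20 % erasure and the
Wilcoxon comparison flags it; the TE-mapped AGO2-bound fraction shows
the two endosiRNA hallmarks — a 5′–5′ overlap mode of exactly 20 nt
(22-nt guides minus the 2-nt 3′ overhangs) and ~75 % 5′ uridine.

`run_pipeline(sim_config(seed = 1), outdir = "out/")` executes all
stages in dependency order and writes every intermediate file plus a
combined `report.json` (TE-class Z-matrix, trap gene set, methylation
time course, siRNA signature, chromatin flags) and a `manifest.json`
with MD5 hashes; identical config + seed reproduces identical outputs.
`inst/scripts/tetrap.R` wraps the same entry point for shell use.

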