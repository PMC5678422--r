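---
title: "Quantifying TE activation, antisense traps and endosiRNA signatures: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TE activation, antisense traps and endosiRNA signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biology being quantified

Acute deletion of *Dnmt1* in mouse embryonic stem cells erases global
CpG methylation within days, mimicking the reprogramming of early
embryos and primordial germ cells. Demethylation releases the
transcriptional silencing of evolutionarily young transposable elements
(TEs) — IAP, ETn, MERVL, MMERVK10C and LINE-1 families — while IAPs
retain relatively more methylation than the genome average. Because many
TE copies lie antisense within transcribed genes, TE activation creates
overlapping sense/antisense transcription: a "trap" that produces
double-stranded RNA, is diced into ~22-nt AGO2-bound endogenous siRNAs
with 5′-uridine bias and 2-nt 3′ duplex overhangs, and restrains TE
activity while repressive chromatin (H3K27me3, H3K9me2) is re-targeted
more slowly.

`tetrap` implements the corresponding quantification stack — TE-class
expression, the per-gene antisense binomial statistic, methylome window
and feature quantitation, small RNA signature analysis, and ChIP tile
enrichment — together with a synthetic-data generator that emulates the
study design so that every stage can be verified end-to-end at desk
scale.

# Coordinate and counting conventions

All internal coordinates are 0-based half-open; BED is read/written
natively, GFF3 and Bismark-coverage positions (1-based) are converted at
the boundary. A single convention end-to-end eliminates off-by-one
drift, and all readers *reject* coordinate violations (with line
numbers) rather than silently clamping.

"Uniquely mapped" is operationalised as MAPQ ≥ 20. A read overlapping
*k* features increments all *k* — no fractional assignment; this is the
simplest auditable rule, and after the ±2 kb genic-exclusion filter the
features of interest are mostly disjoint. Sense means read strand equals
feature strand. With these rules the identity
`sense + antisense = orientation-blind count` holds exactly and is
asserted in the tests.

The ±2 kb filter (TEs intersecting `[gene - 2 kb, gene + 2 kb)` are
removed) avoids attributing read-through or promoter-driven signal to
the TE itself; the boundary is half-open, so a TE starting exactly at
`gene_end + 2000` survives. The filter takes whatever gene set it is
given — protein-coding versus full annotation is the caller's choice.

# Stage models

## TE-class expression

Instance-level counts pass an outlier/noise rule first: an instance is
retained only if its count exceeds 3 in at least one sample. Retained
instances are summed per class and orientation, and the class length is
the summed length of *retained* instances. Normalisation is

\[
\mathrm{log_2 RPM} = \log_2\!\left(
  \frac{c}{(L/10^6)\,(\ell/10^3)} + 1 \right),
\]

with \(c\) the class count, \(L\) the library size and \(\ell\) the
summed class length. The +1 pseudocount makes zero counts map to 0 and
keeps the transform monotone. Class-level Z-scores standardise each
class across samples with the population SD; constant rows are returned
as zeros and flagged rather than producing NaN. A class whose instances
are all dropped is reported *missing*, never as zero expression.

Differential activation is a Welch two-sample *t* on log2 RPM with
Benjamini–Hochberg correction (q < 0.05). The degenerate zero-variance
case that `t.test` refuses is defined explicitly: identical constant
groups give p = 1, constant groups with different means give p = 0.

## The antisense trap statistic

Per gene, sense and antisense read counts are collected, the global
antisense proportion \(p_0 = \sum a_g / \sum (s_g + a_g)\) is the null
rate, and each gene is scored with the one-sided upper-tail exact
binomial \(P(X \ge a_g \mid n_g, p_0)\). One-sided is deliberate: the
trap hypothesis is antisense *excess*; a two-sided test would also flag
depletion. Genes with zero total reads are excluded before BH so they
cannot dilute the FDR; their count is reported. The trap gene set is the
intersection of binomial-significant genes with genes significant (and
up) in a replicate-aware Welch-*t*/BH test on log2 antisense RPM — two
orthogonal lines of evidence, mirroring the common practice of
intersecting an enrichment statistic with a replicate-based differential
test. The KO-vs-WT summary reports both the difference and the ratio of
group antisense proportions, since either reading of "antisense
percentage relative to WT" is defensible.

## Methylome quantitation

Two deliberately different weightings:

* **Windows**: consecutive runs of 50 qualifying CpGs (coverage ≥ 3),
  non-overlapping, left to right per chromosome; the window percentage
  is *call-weighted*, `100 Σ meth / Σ (meth + unmeth)`. Terminal
  sub-50 blocks are dropped.
* **Features**: the *CpG-weighted* mean of per-site percentages over
  qualifying CpGs, requiring ≥ 50 of them — each CpG contributes
  equally regardless of coverage.

TE-class methylation pools all calls across a class's instances
(`100 Σ meth / Σ calls`) and reports a class only if it reaches ≥ 1000
observations in **every** sample of the comparison, making the value
robust and comparable across samples. It is invariant to instance order
and to splitting a class's calls across inputs.

Distribution comparisons use the two-sided Wilcoxon rank-sum test on
window percentages with Bonferroni correction over the family of
comparisons requested in one invocation (the family is
invocation-scoped; callers wanting a per-figure family simply pass those
pairs).

## Small RNA signatures

Reads are filtered to 20–24 nt (inclusive), then partitioned by a
strict first-match hierarchy: rRNA → miRNA → non-repeat genome →
repeat-assignable. The hierarchy order matters (an rRNA fragment
overlapping a miRNA locus is rRNA) and the partition is exact: bin sizes
always sum to the input.

The 5′–5′ overlap signature pairs every plus-strand read (5′ end at
`start`) with every intersecting minus-strand read (5′ end at
`end − 1`) on the same chromosome and tabulates
`o = minus5′ − plus5′ + 1` over 1..30. Pairs are counted with
multiplicity — every qualifying pair, no per-locus collapsing — which
is the simplest exhaustively-checkable definition. Each length's
z-score is computed against the mean and SD of the counts at all
*other* lengths (the convention of small RNA duplex-signature
pipelines); if the background is degenerate (all zeros) the z-score is
NA rather than fabricated. A duplex of L-nt guides with 2-nt 3′
overhangs yields `o = L − 2`, hence the expected mode of 20 for 22-nt
siRNAs; sequences use T internally with U accepted and reported.

Consensus coverage profiles are exact pileups from read offsets;
`match_to_consensus()` locates coordinate-less reads by exact substring
matching (forward, then reverse complement), returning NA for ambiguous
or absent matches — the synthetic reads are generated from the
consensus, so no mismatch model is needed or provided.

Class-level abundances are reads-per-million of the filtered library,
compared between groups by a two-tailed Student's *t* (equal variances)
with `*`/`**` tiers at p < 0.05 / p < 0.005. RPM rather than raw counts
is used because the quantity compared across libraries of different
depth should be depth-normalised.

## Chromatin enrichment

The genome is tiled at 1 kb (terminal partial tiles kept and flagged);
per tile, `log2((obs + 1)/(exp + 1))` with the expected count
`library × width / genome_length` — the count had all reads been
uniform — pro-rated for partial tiles so that `Σ expected = library`.
The pseudocount of 1 on both sides keeps empty tiles defined and decays
with coverage. Class enrichment is the mean tile `log2_oe` over tiles
intersecting ≥ 1 retained instance (tiles spanning two classes count
toward both), with per-class Z-scores across samples computed within a
mark. The KO/WT "≥ 2-fold" rule is evaluated on the linear ratio of
mean observed counts over the class tiles, which is invariant to the
pseudocount and to uniform library scaling.

# The synthetic-data generator

The generator's defaults *are* the study conditions; they are chosen
once and documented here, and the acceptance checks run against them.

* **Genome**: 2 Mb over 2 chromosomes; 200 non-overlapping genes
  (1.5–4 kb); 60 instances × 6 TE classes (0.5–1.2 kb), each class with
  a 1.5 kb random consensus; 50 miRNA and 5 rRNA loci outside genes and
  TEs. 10 % of instances are genic (one per host gene), antisense to
  the host with probability 0.7 — ~21 of the 200 genes carry an
  activated antisense TE, the "trap" truth set. Intergenic instances
  are placed > 2 kb from every gene so they survive the exclusion
  filter. Infeasible layouts fail loudly with the violated constraint.
* **Methylomes**: CpGs on a fixed 1/100 bp grid (20,000 sites);
  coverage ~ Poisson(10); per-site rates ~ Beta with mean equal to the
  day's global level (85/35/20/20 % at days 0/3/6/9) and concentration
  20 — enough spread to be realistic without destroying the mean;
  IAP-like CpGs use the global mean + 0.20 (capped at 1), the
  demethylation-resistance offset.
* **RNA-seq**: multinomial allocation of 10^5 reads over sources: genes
  (log-normal base rates, sd(log) = 0.3), a 6 % pervasive antisense
  background per gene, and TEs at
  `0.15 × base × activation(class, day) × max(1 − m(class, day), 0.05)`.
  The linear coupling to methylation loss is a modelling choice (the
  biology reports level snapshots, not kinetics); the 0.05 floor is
  leaky basal transcription so fully methylated IAPs at day 0 are not
  identically zero. The neutral SINE-like class is
  methylation-insensitive (constant coupling 1) — a genuine negative
  control rather than a class that responds passively to demethylation.
  Activation multipliers (per class, days 0/3/6/9): IAP-like 1/6/10/4
  (activated then resilenced), MERVL-like 1/4/6/6, ETn-like and
  MMERVK-like 1/3/5/5, L1-like 1/2/4/4, SINE-like 1/1/1/1. Read strand
  equals transcript strand; ingestion of real dUTP-stranded data can
  flip strands with `read_reads(..., strand_convention = "reverse")`.
  5 % of reads draw MAPQ < 20.
* **Small RNA**: 4 × 10^5 reads; 90 % miRNA, 2 % rRNA, TE-derived
  duplex siRNAs reaching 3.2 % at the final day (hence 40 % of the
  non-miRNA/rRNA remainder) and scaled across days by the class-summed
  sense × antisense transcript product — the dsRNA-trap model implies
  both strands are required, so classes without antisense genic copies
  produce no siRNA, and the per-day scaling gives the day-0 versus
  late-day differential its signal. Guide lengths are drawn i.i.d. from
  {20:0.05, 21:0.15, 22:0.55, 23:0.15, 24:0.10}; the antisense guide
  starts `overhang` nt before the sense guide in consensus space, so
  the anchored 3′ overhang is exactly 2 nt and the 5′–5′ overlap is
  `L_antisense − 2` (mode 20). The guide 5′ base is forced to U with
  probability 0.75 (else uniform on A/C/G), making the 5′-U fraction
  exactly 0.75 in expectation.
* **ChIP**: 2 × 10^5 reads over 2,000 1-kb tiles; Poisson counts with
  class multipliers. The chronic-response defaults put the day-9 gain
  on IAP-like at 2.5× for H3K27me3 and H3K9me2 (H3K9me3 constitutive at
  1.5×), with milder late gains elsewhere. 2.5 rather than 2.0 for the
  headline condition is deliberate: an unbiased fold estimator centred
  exactly on the 2.0 flag threshold would make the ≥ 2-fold call a coin
  flip; the documented condition should be robustly callable, and
  recovery of an exactly-2.0 configuration is still verified separately
  (within ±10 %).
* **Design**: the default comparison uses 3 replicates per group. Two
  replicates — common in the underlying experiments — leave a Welch
  *t* over 200 genes essentially powerless after FDR control at these
  effect sizes, so 3 is the smallest design under which the documented
  recovery holds.
* **RNG**: one root seed; every sample/stage derives a child stream
  from a string key, so outputs are byte-identical for identical
  (config, seed) and adding a sample never perturbs another's draws.

## What the generator does and does not emulate

It reproduces the *statistical* structure the pipeline assumes: level
and class structure of methylation, strand structure of transcription,
duplex geometry and composition of AGO2-bound libraries, and tile-level
enrichment. It does **not** emulate sequence realism (no sequencing
errors, no mappability/repeat ambiguity — MAPQ is drawn, not earned),
fragment-level coverage biases, biological replicate overdispersion
(replicates differ only by sampling noise), miRNA biogenesis, or
imprinted-locus regulation. Passing tests therefore demonstrate the
correctness and calibration of the *analysis* under the stated
generative model, not performance on real libraries — in particular,
real-data differential calls would need the overdispersion-aware tests
the package deliberately replaces (see below).

# Deviations and numerical choices

* The differential tests of the original analyses (DESeq2 and the
  SeqMonk intensity-difference filter) are replaced by Welch *t* + BH
  (and Student's *t* for small RNA classes, as in the original
  statistics). The package's subject is the filtering, normalisation
  and signature logic around those tests, not negative-binomial
  shrinkage; the replacement is documented in the output metadata and
  here.
* Window percent is call-weighted while feature percent is
  CpG-weighted, mirroring the two distinct phrasings of those
  quantitations; the toy case of one 0 %-site at coverage 30 and one
  100 %-site at coverage 3 (feature value 50 %) discriminates the two
  and is locked in a test.
* Windows are non-overlapping ("consecutive" read as tiling, not
  sliding); the Bonferroni family is the set of comparisons in one
  invocation.
* Pseudocounts: +1 inside the log2 RPM (no stated value upstream;
  required for zeros) and +1/+1 in the tile log2 obs/exp.
* The "counts > 3" cutoff is applied at instance level (kept if > 3 in
  ≥ 1 sample), sitting between instance extraction and class summation.
* "Total length of all TEs" is read per class (matching per-class RPM
  values), not genome-wide.
* Consensus mapping uses exact substring matching — adequate because
  synthetic reads are consensus-derived; no mismatch model.

# Problem sizes and runtime

All defaults run on one CPU in seconds to a few minutes: 20,000 CpGs
(~400 windows), 10^5 RNA-seq reads per sample, 4 × 10^5 small RNA reads
(≥ 6,000 duplexes at day 9), 2,000 ChIP tiles. The test suite's
heaviest property — trap recovery across 100 simulated studies —
completes in a few minutes at these sizes.

# Known limitations

Locus-level (per-instance) differential calls are out of scope, as are
peak calling, input-chromatin normalisation, transcript assembly, miRNA
discovery, and piRNA ping-pong (10-nt) analysis. BAM ingestion is not
built in; aligned reads enter as BED6-like tables (`read_reads()`), and
SAM/BAM users should export such tables upstream. The ≥ 2-fold ChIP rule
and the trap intersection are decision rules, not calibrated error
rates; their operating characteristics under the generative model are
what the acceptance checks report.
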