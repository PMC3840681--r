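---
title: "Methods: transcription landscapes, DSB enrichment, and parent-of-origin analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcription landscapes, DSB enrichment, and parent-of-origin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

meiotrans analyses the relationship between transcription in early meiotic
cells and the landscape of meiotic recombination, in the style of
deep-RNA-seq studies of the *Drosophila* germarium. It consumes per-gene
FPKM tables, a gene annotation, a fixed-window recombination map (cM/Mb),
and localized double-strand-break (DSB) intervals, and asks four
questions: are transcribed genes physically clustered along chromosomes;
do more actively transcribed 100-kb regions recombine more; do DSBs fall
preferentially in transcribed sequence; and do genetically identical
offspring of reciprocal crosses express genes at maternal-like levels?
This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions where the method was genuinely open.

```{r setup, message = FALSE}
library(meiotrans)
library(dplyr)
```

## Conventions and activity calling

All internal coordinates are 0-based, half-open; the GFF3 reader converts
at the boundary (BED shares the internal convention). Strand is carried
but ignored by every analysis — windowing and DSB placement are
strand-agnostic. Absent expression cells are distinguished from zero:
threshold operations treat them as "not expressed" but their count is
reported rather than silently zero-filled.

A gene is *actively transcribed* in a sample when its FPKM is strictly
above a threshold **and** at least `min_reads` (default 10) reads mapped
to it. Two FPKM thresholds are in routine use and both are exposed: 0.1
(permissive; the default of `call_active()`) and 1 (conservative; the
default of the windowed landscape). The bound is strict — FPKM exactly at
the threshold is inactive.

Signed fold change between conditions is `+a/b` when `a >= b` and `-b/a`
otherwise, so its magnitude is never below 1 and the sign indicates the
higher side. Genes with zero FPKM in either condition are excluded from
fold-change ranking rather than patched with a pseudocount: a pseudocount
choice would dominate exactly the extreme ratios the ranking is meant to
surface, while the excluded genes are reported by count.

Multiple-testing correction is Benjamini–Hochberg throughout
(`bh_adjust()`, a thin wrapper over the standard step-up procedure);
differential-expression significance itself is *consumed*, not computed —
the package applies FDR control and the `q < 0.05` threshold to per-gene
p-values produced upstream (or, for synthetic crosses, by a two-sample
t-test on log FPKM of replicate libraries).

## Clustering of expressed genes: the runs test

Genes are ordered by (chromosome, start, end, id); overlapping genes each
contribute one label in that order. With genes labelled active/inactive,
the Wald–Wolfowitz runs test compares the observed number of maximal
same-label stretches with its randomization expectation
`E[R] = 2 n1 n2 / n + 1` and variance
`Var[R] = 2 n1 n2 (2 n1 n2 − n) / (n^2 (n − 1))`, using the normal
approximation for a two-sided p. Physical clustering appears as fewer
runs than expected (`z < 0`).

Because chromosome ends are not biological switches, the default mode
counts runs *within* each chromosome and sums both the counts and the
per-chromosome moments; a `genome` mode treating the gene order as one
concatenated sequence is provided since either reading of a genome-wide
runs test is defensible. Chromosomes carrying a single label contribute
their runs to the totals but are excluded from the z statistic, which is
undefined for them. `mean_cluster_size()` reports the average length of
maximal active runs — the "consecutive co-expressed genes" summary — at
whichever threshold produced the calls.

## Windowed transcription landscapes

`bin_genome()` tiles each chromosome with adjacent windows (default
100 kb, the scale at which fixed-window recombination maps are typically
estimated); the terminal partial window is kept but flagged, and excluded
from correlations by default because rates are per-Mb normalized while a
short window's metrics are not.

`window_metrics()` computes three measures per window:

* `n_transcribed` — transcribed genes assigned to the window by their
  midpoint, so each gene counts exactly once;
* `kb_transcribed` — kilobases of the window covered by at least one
  transcribed gene's genomic footprint (interval union clipped to the
  window: overlapping transcripts count once);
* `ota` — overall transcriptional activity, log10 of the summed
  FPKM × transcript length over the window's (midpoint-assigned)
  transcribed genes.

Two deliberate asymmetries: the *genomic* span (start–end) feeds
`kb_transcribed`, because it measures transcribed territory, while the
annotated *exonic* transcript length feeds OTA, because FPKM is
per-transcript-kilobase; and midpoint assignment is used for counting and
OTA (avoiding double-counting a gene's FPKM × length across windows)
while footprints are clipped for `kb_transcribed`. OTA of a window with
no transcribed base is undefined (`NA`), not −∞: correlations use only
defined values (and report how many were dropped), while the multiple
regression imputes `min(OTA) − 1` so that untranscribed windows remain in
the model as a floor category (flagged, and switchable to row dropping).

Associations with the recombination map use Spearman rank correlation
with average-rank ties (`correlate_with_recombination()`), an OLS
multiple regression of rate on the three metrics with per-coefficient
t-tests (`landscape_regression()`; raw variables by default, with a
`rank = TRUE` option since a rank regression is an equally defensible
reading), and a two-sided Mann–Whitney contrast of rates in windows with
zero versus one-or-more transcribed genes
(`zero_vs_nonzero_transcription()`).

## DSB enrichment against a random-placement null

`build_partition()` divides the genome into five exhaustive categories:
*intergenic*, *silent* (gene with FPKM < 0.001 — a conservative
"no detectable transcription" bound), and *low/medium/high* transcription,
obtained by ranking active genes on the target-potential product
FPKM × transcript length and splitting at count tertiles by default. The
cuts accept any strictly increasing quantiles; note that published
analyses have used group sizes (e.g. 33/46/21% of active genes) implying
cut values that were never stated, so the tertile default will not
reproduce such proportions and no attempt is made to reverse-engineer
them. Where genes of different categories overlap, the higher category
wins the shared bases (deterministic, with the contested base count
reported); the category footprints partition the genome exactly.

Events (each ≤ 500 bp) are reduced to their midpoints for classification.
The Monte-Carlo null (`monte_carlo_null()`) places the same number of
midpoints uniformly over the concatenated genome in each of 10,000
replicates (the study-scale default) and tallies categories, making
observed and expected strictly commensurable — the same midpoint rule on
both sides. *Relative presence* is observed/expected; the empirical
p-value doubles the smaller tail with add-one correction,
`p = min(1, 2 (1 + #as-or-more-extreme) / (1 + R))`, so it is
conservative, two-sided, and never exactly zero (the floor at 10,000
replicates is 2/10,001).

## Parent-of-origin effects and allele-specific expression

A gene shows a *maternal-like* parent-of-origin effect when the
genetically identical offspring of the two reciprocal crosses differ
significantly (q < 0.05) **and** the direction of the offspring
difference matches the direction in which the maternal strains differ.
Maternal-like genes are further split by which maternal strain they
track more closely — the cross with the smaller |log(offspring /
maternal-parent FPKM)|. An earlier candidate rule (nearest parent to the
mean offspring level) was discarded during development because a gene
tracking both mothers symmetrically sits near the midparent and the
nearest parent is then arbitrary; the per-cross log-ratio compares each
offspring with its own mother and is well defined whenever the parents
differ. Significant genes with zero parental difference or exactly
balanced tracking are classed "unresolved" and reported.

Allele-specific expression replaces full read re-mapping with a
locus-anchored exact-match classifier (`assign_reads()`): each read is
compared, with zero mismatches, against the substrings of both parental
haplotypes at its position. Matching exactly one parent assigns the read;
matching both (no covered SNP) is ambiguous; and if *either* parental
reference contains an `N` anywhere under the read it is excluded outright,
even when the other parent matches — an `N` makes the uniqueness of the
match undecidable. This preserves the decision rules of an
alignment-based pipeline (zero mismatches, uniqueness, N-exclusion) at
desk scale; it is a simplification in that reads are anchored at their
true locus rather than re-mapped genome-wide.

Per-gene allelic ratios `reads_A / (reads_A + reads_B)` are computed only
for genes with at least 100 allele-specific reads (the accuracy floor for
a ratio). Genome-wide allele excess is tested by a two-sided sign (exact
binomial) test of per-gene ratios against 0.5 — the package's choice of
test for an excess whose published analyses leave the statistic unnamed —
and the cross-to-cross shift by the paired Wilcoxon signed-rank test,
implemented with the tie-corrected normal approximation so the Z
statistic is exposed (`paired_level_test()`).

## Novel-transcript filter cascade

`filter_cascade()` applies, in fixed order: (1) detected (FPKM > 0 by
default; a mapped-read rule is available since "detected" is ambiguous)
in ≥ 2 samples; (2) FPKM > 1 in ≥ 1 sample; (3) length > 300 bp,
repetitive fraction ≤ `max_repetitive`, and splice-junction support.
Repetitiveness and junction reliability arrive as candidate-level scores
from the upstream assembler and are thresholded here, since in practice
they are assessed by inspection. The cascade is monotone by construction;
the final curator step (visual inspection of exon–intron structure) is
deliberately out of algorithmic scope. Per-stage survivor counts and id
sets are returned.

## The synthetic-data generator

Every input the pipeline consumes can be generated with planted effects
(`sim_config()` and the `simulate_*()` functions), so that recovery of
the planted signal is a testable property. One global seed drives each
generator through a derived, restored-on-exit RNG state: fixed seed ⇒
bit-identical outputs, and the caller's RNG is never disturbed.

Key default choices, made once as plausible desk-scale study conditions:

* **Genome**: three chromosomes (one X, 8 Mb; two autosomes, 10 Mb each),
  2,000 non-overlapping genes with lognormal spans (median 3 kb), exonic
  length a uniform 50–95% fraction of the span.
* **Activity clustering**: a two-state Markov chain along gene order with
  persistence 0.7 — the simplest mechanism producing physically clustered
  co-expression; persistence 0 gives independent states, the null of the
  runs test.
* **X excess**: stationary activity probabilities 0.604 (X) versus 0.553
  (autosomes), the reported transcribed-gene proportions in early
  meiotic tissue.
* **Expression**: active genes draw lognormal FPKM (meanlog 3, sdlog 1.5,
  mean ≈ 60); eight samples (parental strains A and B plus both
  reciprocal crosses, in Early and Late condition) add per-gene strain
  effects (log-SD 0.5), condition shifts, and per-sample lognormal noise;
  mapped reads are Poisson at 20 reads per FPKM per transcript kb.
* **Maternal effects**: 10% of genes shift offspring expression from the
  midparent toward the maternal parent by 70% on the log scale.
  Reciprocal crosses are simulated with 4 replicate libraries per cross
  at 10% library CV, and the reciprocal-difference p comes from a Welch
  t-test on log FPKM — chosen so that strongly strain-divergent planted
  genes are recoverable after FDR control while the null stays calibrated.
* **Recombination**: window rate = max(0, 2 cM/Mb + 0.2·genes +
  0.05·kb + 0.1·OTA + bell-shaped mid-arm trend (amplitude 2) + N(0, 1)),
  on full 100-kb windows. The default gene effect is ≈ 0.5 noise-SD per
  window — detectable but not overwhelming.
* **DSBs**: 5,610 events, drawn category-first with probability
  ∝ weight × footprint (equal weights ⇒ uniform placement), midpoint
  uniform within the category footprint, width uniform in 50–500 bp. The
  default weights (low 2, medium 1.5, high 1.2, silent 1,
  intergenic 0.9) emulate the reported preference of DSBs for transcribed
  — and especially lowly transcribed — genes.
* **Haplotypes and reads**: parent B equals parent A with substitutions
  at 5 SNPs/kb (a typical between-strain divergence); the *reference*
  copies additionally mask bases to `N` at rate 0.001, while reads
  (120 bp, error-free) are sampled from the unmasked true haplotypes.
  Reads are error-free by design: the zero-mismatch rule would otherwise
  confound sequencing error with allelic origin, which is precisely the
  variable under test; an error model is a noted extension.

What the generator does *not* emulate: isoform structure (one transcript
per gene), fragment-level FPKM estimation noise, sequencing error,
mapping bias, GC or mappability covariates, and realistic
recombination-map autocorrelation beyond the smooth bell trend. Passing
recovery tests therefore demonstrates that the *inference machinery* is
correct and calibrated, not that real data meet its assumptions.

## Numerical choices and degenerate inputs

* Empirical p-values carry the add-one correction and are never zero;
  expected counts of zero with positive observed counts flag relative
  presence as undefined rather than dividing by zero.
* The runs test requires both labels for z/p; single-label input returns
  cluster statistics with an explanation instead of NaN.
* Spearman p-values use the t approximation (`exact = FALSE`) because
  tied ranks are the norm in count metrics.
* The signed-rank test drops zero differences, errors when all
  differences are zero, and warns below 10 informative pairs where the
  normal approximation is unreliable.
* Fold change refuses zeros rather than guessing a pseudocount.
* Degenerate 2×2 contrasts (an empty margin) and constant or collinear
  regression predictors are errors naming the offender.

## Problem sizes in the test-suite and acceptance runs

The packaged checks run at the study's stated analysis sizes where the
statistic depends on them — 5,610 DSB events against 10,000 null
replicates, 100-kb windows, the 100-read allelic floor, 10,000 reads for
assignment — while simulated genomes use a few megabases and a few
hundred to a few thousand genes, sizes at which every planted effect is
comfortably detectable and the full suite runs in minutes. Calibration
properties (type-I error of the runs test and of the landscape
correlation under null effects) are measured over hundreds of seeds,
giving Monte-Carlo standard errors near 0.01 on a nominal 0.05 rate.

## Known limitations

* The exact (non-asymptotic) runs-test distribution is not implemented;
  with very few genes per chromosome the normal approximation degrades.
* The midpoint rule makes window counts and DSB classification
  insensitive to genes or events straddling boundaries; at 100-kb windows
  and ≤ 500-bp events the effect is negligible, at much finer windows it
  would not be.
* Recombination maps are consumed, never estimated; DSB events are taken
  as localized intervals with no crossover/non-crossover distinction.
* The maternal-like classifier tests marginal reciprocal differences
  gene by gene; it does not model shared maternal factors across genes.
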