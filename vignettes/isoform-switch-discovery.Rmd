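---
title: "Regulator-conditioned isoform switch discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulator-conditioned isoform switch discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Epithelial splicing regulators such as ESRP1 reshape the isoform
composition of many genes at once: as regulator expression rises across a
panel of cell lines or tissues, some genes shift from one dominant splice
isoform to the other. `switchscan` implements the computational chain used
to find such regulator-coupled switches in bulk RNA-seq — TPM
normalization, per-gene isoform fractions, two complementary switch
statistics, cassette-exon PSI from junction reads, splice-event typing,
and downstream fold-change-stratified survival analysis — together with a
synthetic cohort generator so every stage can be validated against known
ground truth without any external download.

```{r, eval = FALSE}
library(switchscan)
cohort <- simulate_cohort(cohort_config(seed = 1))
tpm <- tpm_normalize(cohort$counts, cohort$ground_truth$effective_lengths)
fractions <- isoform_fractions(tpm)
scores <- correlation_switch_scores(cohort$regulator, fractions, top_k = 20)
head(scores)
```

# The switch statistics

## Correlation-difference score

For a gene with two designated isoforms and per-sample relative frequencies
$f_1(s)$, $f_2(s) = 1 - f_1(s)$, the score is

$$\Delta r \;=\; r\!\left(R, f_1\right) - r\!\left(R, f_2\right) \in [-2, 2],$$

where $r$ is the Pearson correlation and $R$ the regulator's expression
across samples. A gene whose dominant isoform tracks the regulator
perfectly reaches $|\Delta r| = 2$ (for complementary two-isoform
fractions, $\Delta r = 2\,r(R, f_1)$ identically). Genes whose two
designated isoforms carry too little of the gene's output — mean
$f_1$ + mean $f_2$ below `min_total_fraction = 0.5` — are excluded before
ranking, as are genes with undefined correlations (fewer than 3 usable
samples or zero variance). Ranking is by descending $\Delta r$ with ties
broken lexicographically by gene id; the default report flags the top 20.

**Orientation.** $\Delta r$'s sign depends on which isoform is called
"isoform 1". By default the package orients each pair so isoform 1 is the
isoform favoured in regulator-high samples (median split); true switches
then score near $+2$ and descending rank order recovers them. This
data-driven orientation makes signed null scores slightly positive by
selection (the same phenomenon as taking a maximum of two correlated
noisy quantities), which is why null-calibration checks use either the
orientation-free $|\Delta r|$ or a fixed designation
(`orient_isoforms = FALSE`, under which $\Delta r$ is antisymmetric in the
pair and centred at zero for null genes). Output headers state the
convention.

Significance is deliberately score-based (top-$K$), matching discovery
practice for this statistic; an optional permutation extension
(`n_perm > 0`) permutes the regulator across samples, pools $|\Delta r|$
over genes and permutations into one empirical null, and reports
per-gene permutation p-values with Benjamini–Hochberg adjustment.

## Rank-based two-group (kTSP-style) score

When the cohort is dichotomized into regulator-low and -high groups, the
package scores each isoform pair by
$\big|\,p_\text{low} - p_\text{high}\big|$, where $p_g$ is the empirical
probability that $f_1 > f_2$ within group $g$ (ties count 0.5). This is
the two-isoform special case of the top-scoring-pairs idea: it depends
only on the within-sample ordering of the two isoforms, so it is invariant
under any strictly monotone transform of the fractions and completely
insensitive to expression scale. A score of 1 means the dominant isoform
flips between groups in every sample. Default report: top 100.

The two rankings answer slightly different questions (continuous gradient
vs group contrast); the analysis scripts report both and their overlap
rather than privileging one.

# PSI from junction reads

For a cassette exon, inclusion is supported by two exon–exon junctions and
skipping by one, so raw junction counts over-weight inclusion. The package
uses the length-normalized form

$$\psi = \frac{I/L_I}{I/L_I + E/L_E}, \qquad L_I = 2,\; L_E = 1
\text{ by default (overridable)},$$

which reduces to $I/(I+E)$ at equal lengths. When both counts are zero the
event is unobserved and $\psi$ is missing — never 0, which would
fabricate skipping evidence. The TPM-ratio form of inclusion (the
inclusion isoform's relative frequency from `isoform_fractions()`) is also
available; reports label which estimator they used. Group comparisons of
PSI use the classical pooled-variance two-sample t-test, with the
degenerate zero-variance case flagged explicitly rather than erroring.

# Splice-event classification

`classify_event()` types the *local* difference between two exon chains of
one gene into SE, RI, A3, A5, AF, AL, MX, `identical`, or `complex`.
Internally the two sorted chains are reduced to their differing middle by
stripping the longest common prefix and suffix of identical exons; the
shape of the middle decides the type. Conventions, chosen once and tested
exhaustively against an independent rule-checker:

* Coordinates are 0-based half-open internally (interval arithmetic is
  simplest there); all GTF I/O converts to/from 1-based inclusive at the
  boundary, and the conversion is a bijection.
* A3/A5 and AF/AL are **transcription-relative**: on the minus strand the
  donor of an internal exon sits at its genomic *start*, so a difference
  there is A5, and the transcription-first exon is the genomically last
  one. Consequently, flipping only the strand flag swaps A3↔A5 and AF↔AL,
  while mirroring coordinates *and* flipping the strand (the same
  transcript read in the same transcription order) preserves every label.
* A difference that could read as either a terminal-exon skip (SE) or an
  alternative first/last exon resolves by position: terminal differences
  are AF/AL, internal ones SE.
* Differences confined to a transcript-terminus coordinate (TSS or 3' end,
  which are not splice sites) are classed with AF/AL as degenerate
  overlapping terminal-exon variants, keeping the function total.
* Anything compound (multi-exon middles, overlapping substitutions without
  a shared splice site) is `complex`: reported, never silently typed.

Classification is symmetric in its two arguments, and pairwise only: the
pipeline scores designated two-isoform pairs, so full multi-isoform event
generation is out of scope.

# Survival analysis and the DE filter

Patients are stratified by the tumor/matched-normal expression ratio of a
chosen feature, with the boundary **inclusive** (a ratio of exactly 2
counts as ≥ 2-fold, following the printed symbol); patients with a
non-positive normal value have no defined ratio and are excluded with a
warning. Kaplan–Meier curves and the two-group log-rank test are computed
with the `survival` package (`survfit`/`survdiff`) behind thin,
validated wrappers; `event = 1` means death observed. Times are months.

The differential-expression filter applies a per-gene Welch t-test on
`log2(x + 1)` with Benjamini–Hochberg adjustment, and passes a gene only
when the adjusted p-value is **below 0.01** and the absolute log2 fold
change **strictly exceeds 1.0** — a gene at exactly 1.0 fails. Welch was
chosen because the replicate variances of the two conditions need not be
equal and the test engine behind the published thresholds is unspecified;
the thresholds themselves are applied with exactly the printed strictness.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the scoring
pipeline assumes, not any particular dataset:

* **Regulator**: log-normal TPM across samples (`meanlog = log 50`,
  `sdlog = 1`), standardized on the log scale to $z_s$.
* **Switch genes**: inclusion-isoform fraction
  $f_1(s) = \text{logistic}\!\big(\beta\,(z_s - c)\big)$ with defaults
  $\beta = 4$, $c = 0$. The logistic link is the minimal bounded monotone
  choice for a fraction that tracks a covariate; $\beta = 4$ gives a
  strong but noisy-count-limited association, and $\beta = 0$ is the
  exact null.
* **Null genes**: constant $f_1$ drawn once from U(0.2, 0.8).
* **Counts**: negative binomial with mean
  `gene_expression × fraction × length/1000` and shared dispersion 0.1 —
  the standard bulk RNA-seq noise model. Per-gene expression is
  log-normal (`meanlog = log 500`).
* **Structures**: every gene is a 3-exon inclusion isoform (200/72/300 bp
  exons; the 72-nt middle cassette mirrors the studied exon's length)
  versus the 2-exon skipping isoform on its own contig, so every pair
  classifies as SE and carries exactly one cassette event.
* **Junctions**: per-sample total depth Poisson(50), split binomially with
  inclusion probability $2f_1/(1+f_1)$ — two inclusion junctions versus
  one skipping junction — so the length-normalized PSI estimator is
  centred on $f_1$.
* **Determinism**: one global seed; each gene draws from its own
  counter-based substream, so enlarging the cohort never reshuffles
  existing genes.

Default cohort size is 18 samples with 20 switch genes among 2000, the
panel geometry the discovery statistics are meant for; the regulator's
median split (9/9) and an explicit preset split (e.g. 5/13) are both
supported because real panels are dichotomized both ways.

`simulate_survival_cohort()` generates matched tumor/normal pairs whose
log2 ratio is Gaussian (mean 0.3, sd 1.5, putting roughly a third of
patients past 2-fold), exponential event times with the up-regulated
stratum's hazard multiplied by the chosen ratio (baseline median 40
months), and independent uniform censoring on (0, 120) months. Exponential
times make the stratum medians available in closed form
($\ln 2 / \lambda$), which the tests use as an oracle.

**What the generator does not emulate**: batch effects, library-size and
GC biases, more than two isoforms per gene, correlated genes, read-level
alignment/quantification error, informative censoring, covariate-dependent
hazards. Passing tests therefore demonstrate that the statistics recover
the signals they define under their own noise model — not pipeline
performance on raw reads or on any specific clinical cohort.

# Numerical and validation choices

* Pearson correlation with fewer than 3 paired observations is undefined
  by fiat; undefined fractions/PSI propagate as missing, never as zero.
* TPM columns sum to $10^6$ within relative $10^{-6}$; all-zero samples
  stay zero with a warning rather than producing NaN.
* Ties in rankings break lexicographically by gene id, making every
  ranking deterministic.
* The test suite validates each statistic against an independent oracle:
  brute-force Pearson sums, exhaustive rank-pair counting, a separately
  written splice-event rule-checker run over *every* pair of exon chains
  of ≤ 4 exons on an 8-boundary grid (32,258 pairs, both strands), hand
  product-limit/log-rank tabulations, and closed-form exponential medians.
* Calibration checks use fixed-seed Monte Carlo at sizes chosen for
  stable binomial confidence intervals: 1,500 null genes × 200 regulator
  permutations for the $|\Delta r|$ exceedance rate, 500 replicate
  cohorts for log-rank type-I error, and 10 × 2,000-gene cohorts for
  planted-signal recovery. The DE-filter sensitivity check plants 50
  four-fold genes among 2,000 with low replicate noise (log-sd 0.05,
  4 replicates per condition), where the strict thresholds should and do
  recover all of them.

# Known limitations

* Two isoforms per gene per score; genes with more isoforms must have a
  designated pair (the expression filter then guards against pairs that
  carry little of the gene's output).
* The event classifier types single local differences; compound events
  are reported as `complex` rather than decomposed.
* The kTSP-style score is a faithful reimplementation of the
  top-scoring-pair idea for the two-isoform case, not a port of any
  specific software's multi-gene ranking.
* Amplicon prediction is exact-match (with an optional mismatch budget)
  on spliced cDNA; it does not model primer thermodynamics or genomic
  (intron-spanning) amplification.
* Effective length for TPM is the annotated exonic length; no
  fragment-length correction is applied.
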