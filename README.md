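# switchscan

Detection of splicing-regulator-coupled isoform switches in bulk RNA-seq
cohorts, with the downstream analyses such a discovery feeds: splice-event
typing, junction-based PSI, fold-change-stratified survival, a strict
differential-expression filter, and in-silico RT-PCR verification of
isoform-discriminating primers.

## Who this is for

Computational biologists studying alternative splicing across a panel of
samples (cell lines, tissues) that spans a gradient of a splicing
regulator's expression — e.g. ESRP1 in epithelial–mesenchymal contexts —
who want to ask: *which genes switch their dominant isoform as the
regulator changes, and does the switch matter downstream?*

## The statistics at the core

For each two-isoform gene with per-sample relative frequencies
`f1(s), f2(s) = 1 − f1(s)` and regulator expression `R(s)`:

* **Correlation-difference score**
  `Δr = r(R, f1) − r(R, f2) ∈ [−2, 2]` (Pearson), computed after a
  low-expression filter (mean f1 + mean f2 ≥ 0.5) and ranked descending;
  a perfect regulator-tracking switch scores 2. Isoform 1 is oriented as
  the isoform favoured in regulator-high samples (documented, switchable).
* **kTSP-style two-group score** `|p_low − p_high|` where `p_g` is the
  within-group probability that `f1 > f2` (ties 0.5) — a rank-based
  top-scoring-pair statistic for the dichotomized cohort.
* **PSI** of a cassette exon from junction reads,
  `ψ = (I/2) / (I/2 + E)` by default (two inclusion junctions vs one
  skipping junction), undefined — not zero — when unobserved.
* **Splice-event classifier** assigning SE / RI / A3 / A5 / AF / AL / MX
  (strand-aware, transcription-relative) to any isoform pair.
* **Survival**: ≥ 2-fold tumor/normal stratification (boundary
  inclusive), Kaplan–Meier curves, two-group log-rank test; **DE filter**:
  Welch t on log2(x+1), BH adjustment, pass iff adjusted p < 0.01 and
  |log2FC| > 1.0 strictly.

A synthetic cohort generator (`simulate_cohort()`,
`simulate_survival_cohort()`) emulates the assumed statistical structure —
regulator gradient, logistic-link switch genes among null genes,
negative-binomial counts, junction reads, paired expression with
exponential survival — with full ground truth, so the whole chain is
testable offline.

## Worked example

The `analysis/` scripts run the full chain on the synthetic cohort
(18 samples, 20 planted switch genes among 2000, seed fixed in the
scripts):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_switch_scan.R
Rscript analysis/03_events_and_psi.R
Rscript analysis/04_survival.R
Rscript analysis/05_amplicon.R
```

Output printed by the scripts (tables land under `results/`):

```
Scored 2000 genes. delta_r range of top 20: 1.34-1.45.
Planted switch genes in delta_r top 20: 19/20; in kTSP top 100: 20/20.
Overlap of the two top lists: 19 genes.

Event types among top 20 switch pairs: SE=20.
G0001 cassette PSI: 0.09 (low group) vs 0.86 (high group), t = -13.40, p = 4.11e-10.

Strata: 9 up-regulated (>= 2-fold) vs 28 other.
Log-rank chi-square = 6.80, p = 0.00911.
DE filter: 50/2000 genes pass (50 of 50 planted recovered).

Products: V2_skipped_synthetic = 222 bp, V3_inclusion_synthetic = 294.
Length difference between isoforms: 72 nt (= cassette length).
```

Reading this: the correlation-difference ranking recovers 19 of the 20
planted switches in its top 20 (one planted gene lands just outside; the
group-based score catches all 20 in its top 100); every top pair is
correctly typed as a cassette-exon (SE) event; the cassette's PSI
separates cleanly between regulator-low and -high samples; patients whose
tumors up-regulate the surrogate ≥ 2-fold show significantly worse
survival under the simulated 3-fold hazard; and the primer pair that
brackets the 72-nt cassette predicts products of 222 vs 294 bp, so a
single RT-PCR distinguishes the isoforms on a gel.

See `vignettes/isoform-switch-discovery.Rmd` for the models, parameter
conventions, and what the synthetic cohorts do and do not emulate.

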