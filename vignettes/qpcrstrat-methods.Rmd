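---
title: "Methods: CT preprocessing, ddCT differential expression and patient stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT preprocessing, ddCT differential expression and patient stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrstrat)
```

## The problem this package addresses

Low-density qPCR arrays (e.g. TaqMan microfluidic cards) measure hundreds of
miRNA assays per sample as cycle-threshold (CT) values: the PCR cycle at which
fluorescence crosses a detection threshold, so *lower* CT means *higher*
abundance, on a log2 scale. Small clinical case/control cohorts profiled this
way pose a specific chain of analysis problems:

1. CT values near the instrument ceiling are unreliable and must be censored,
   which leaves the data with an informative missingness mask;
2. per-sample loading and RNA-quality differences must be removed
   (normalization plus an endogenous-control reference);
3. group differences are tested on ΔCT and reported as signed 2^-ΔΔCT fold
   changes under multiple-testing control;
4. heterogeneous patient populations may carry the expression signature in
   only a subset of patients, which motivates cluster-based stratification and
   re-testing within the discovered subgroup;
5. molecular markers are screened against clinical covariates (pain score,
   comorbidities, medication) with a rank-based correlation network.

`qpcrstrat` implements this chain end to end, and ships a seeded synthetic
cohort generator with a recorded ground truth so that every stage is testable
without access to patient data.

## Model and procedure

### Censoring and detection filtering

CT values at or above a threshold (default **32 cycles**, the common vendor
recommendation for these arrays) are treated as undetected. The values are
retained but masked; the mask only ever grows, and every downstream statistic
excludes masked cells (pairwise deletion, no imputation). The rationale is
that a censored CT carries no magnitude information — treating "32+" as a
number would bias every mean it enters.

Assays must be detected in at least a configurable fraction (default **0.5**)
of the samples of *each* cohort to be tested. This inclusion rule is an
explicit pipeline addition — array exports carry many assays never expressed
in blood, and a well-defined test requires a minimum per-group sample size —
and it is logged and recorded in the run manifest.

### Quantile normalization under censoring

Samples are forced to share one CT distribution by rank alignment, restricted
to detected cells. Within each sample the detected values' ranks are mapped
onto a target distribution: the mean across samples of within-sample order
statistics, aligned on the quantile grid $(r - 0.5)/n$ and linearly
interpolated when samples differ in detected count. Ties receive the average
of their target values. On fully detected matrices with equal counts this is
exactly the classic sort/row-mean construction (and agrees with
`limma::normalizeQuantiles`); the grid-interpolation extension is the
standard, deterministic way to keep the procedure well defined when detected
counts differ. Undetected cells are never touched.

### Endogenous control and ΔCT

The reference is data-driven: among assays detected in 100% of samples, the
**10** assays with the lowest standard deviation across samples form the
endogenous-control set, and their per-sample mean CT is subtracted to give
ΔCT. Ties in SD are broken lexicographically by assay id so that the
selection is deterministic and invariant to row order. By construction ΔCT is
invariant under any per-sample additive CT shift, which is precisely the
loading artifact the reference is meant to remove.

Whether the lowest-SD ranking should be computed before or after quantile
normalization is genuinely open; the package defaults to **normalized CT**
(normalization precedes referencing in the processing order) and exposes
`ref_stage = "censored"` for the other reading.

### Differential expression

Per assay, the difference in ΔCT between groups is tested with a two-tailed
independent-samples *t*-test. The default variant is the **pooled-variance
(Student)** test — the conventional meaning of "independent samples t-test"
in this literature — with Welch available by flag. Benjamini–Hochberg
step-up adjustment is applied across tested assays, and features are flagged
at an adjusted-p threshold of **0.05** by default (recorded in the manifest;
the emulated analysis style never states its threshold).

Fold change is reported with the signed 2^-ΔΔCT convention:
$r = 2^{-\Delta\Delta CT}$, reported as $r$ when $r \ge 1$ and $-1/r$
otherwise, so magnitudes are always ≥ 1 and a positive ΔΔCT (higher CT in
patients, i.e. lower abundance) yields a negative fold change. A subtlety of
the emulated workflow is that fold changes are quoted *from raw (censored)
CT* while tests run on normalized ΔCT; the package wires both paths through
one pair of config keys (`fc_source = "raw"`, `test_source = "normalized"`
by default) and lets either be switched.

Analyte (cytokine) panels reuse the same test/BH machinery on
concentrations, with fold change as the unsigned patient/control mean ratio
(these are linear-scale concentrations, not cycles). Tests default to raw
concentrations — the emulated analysis states no transform — with an
optional log transform.

### Stratification

The clustering matrix is the per-sample log2 relative expression over the
significant assays: $\mathrm{rel}(i,s) = -(\Delta CT(i,s) -
\overline{\Delta CT}(i, \mathrm{controls}))$, i.e. each sample's log fold
change versus the control mean — the only per-sample reading of a
"log-transformed fold change" heatmap. Samples are clustered
agglomeratively (default **euclidean / average linkage**; unstated in the
emulated analysis, both configurable and recorded) and cut to **k = 3**
groups. Missing cells are imputed as 0 — "no change" on the centered
scale — *only* inside the distance computation; the exported matrix keeps
them missing.

The "signature group" for unattended runs is the patient-only group with the
largest patient fraction (ambiguous when no patient-only group exists). The
subgroup re-test compares that group against *all* other samples, controls
included, reusing the differential machinery unchanged — the comparison that
surfaces markers confined to the subgroup and diluted away in the
all-patients contrast.

### Correlation screen

miRNA "expression" enters the screen as −ΔCT (monotone in abundance and
rank-equivalent under Spearman to any 2^-ΔCT transform). Binary flags enter
as 0/1 and disease type as 1/2. Spearman's rho is computed tie-corrected
(Pearson on average ranks) after pairwise deletion, with a minimum of **5**
complete pairs, and p-values from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$. All cross-namespace pairs
(miRNA×clinical, miRNA×analyte, analyte×clinical) and clinical×clinical
pairs are tested; BH adjustment is applied **within each namespace-pair
family** (the emulated scheme is unstated; a global family would let the
huge miRNA×clinical family drown the small analyte families), and pairs are
kept at adjusted p < **0.01**. By default only patients enter the screen
(clinical covariates are patient-specific); `use_samples = "all"` is
available for cohort-agnostic questions.

## The synthetic cohort: what it emulates, and what a green test establishes

The generator is a stated world, not a tuning dial. Its defaults encode the
emulated study shape: 41 patients / 20 controls over 758 assays; 18
differential assays at a 2-cycle ΔCT shift, 90% down-regulated, carried by a
60% patient subgroup; 5 subgroup-only markers at half shift; 20
reference-like assays at a tenth of the 0.5-cycle measurement noise;
baselines uniform on 20–31 cycles with censoring at 32; a ten-analyte
log-normal panel (CV 0.4) with three analytes elevated two-fold, two of
which couple to the 0–10 pain score through a latent severity with a
Gaussian-copula loading calibrated ($r = 2\sin(\pi\rho_s/6)$) to a Spearman
rho of 0.6; and comorbidity-linked assays (1.5-cycle shifts on carriers of
cohort-balanced flags) disjoint from the disease signature.

Two generator choices deserve justification:

* **Effect-carrying assays are drawn from baselines below
  `censor_threshold - shift - 2·noise_sd`.** A planted signature must remain
  quantifiable after the shift to be a signature at all; the emulated
  study's significant assays were by construction robustly detected. Without
  this constraint ~14% of down-shifted assays would censor out in carriers
  and recovery statistics would measure baseline luck, not the method.
* **Comorbidity flags that shift assays are cohort-balanced.** The emulated
  analysis observed that comorbidity-associated miRNAs did not overlap the
  disease signature; linking assays to patient-only medication flags would
  recreate exactly that confound. Medication flags exist in the sheet (for
  the correlation screen) but shift nothing by default.

What the synthetic world does *not* emulate: plate/batch effects,
amplification-efficiency differences, correlated assay noise
(co-regulation), non-Gaussian CT error, missing-not-at-random dropout beyond
the ceiling mechanism, and any real biological covariance between analytes.
A green recovery test therefore establishes that the pipeline's inference
machinery is correct and calibrated under its own assumptions — not that
those assumptions hold on any particular instrument's output.

## Numerical and design choices

* ΔΔCT sign convention: ΔΔCT = mean ΔCT(patients) − mean ΔCT(controls);
  fold change +1 exactly at ΔΔCT = 0; outputs never fall in (−1, 1).
* BH is implemented as the literal step-up (`cummin` over the reversed
  sorted sequence), NA-transparent, validated against `stats::p.adjust` and
  a brute-force oracle.
* Zero-variance t-test degeneracies: equal means give t = 0, p = 1; unequal
  means give p = 0 (the limit of the statistic).
* Clustering determinism: `stats::hclust` is deterministic given the input
  order; group ids are renumbered by first appearance, so partitions (not
  numberings) are the reproducible object. Continuous noise makes exact
  distance ties measure-zero; the permutation-equivariance tests use noisy
  data for that reason.
* Quantile-normalization interpolation tolerance: sorted detected vectors of
  equal-count samples agree exactly; unequal counts agree through the
  interpolated grid (1e-9 in tests).
* Recovery bookkeeping: sensitivity is measured on the 18 full-shift
  assays; the false-discovery proportion counts as true any assay with a
  planted cohort-linked shift (full- or half-shift) — a half-shift marker
  reaching significance is a detected real effect, not a false discovery.
  Fold-change recovery of the planted 4-fold magnitude is measured in the
  signature-subgroup-vs-rest comparison, because the all-patients contrast
  sees the planted effect diluted by the 40% non-carriers (≈ 2.3-fold at
  defaults) by design.
* The stratification phenomenon is asserted qualitatively, as in the
  emulated analysis: all half-shift markers significant in the
  subgroup-vs-rest comparison and at least one of them missed by the
  all-patients comparison. A 1-cycle shift in 25 of 41 patients yields a
  noncentral t around 3.5 in the all-patients test — each marker clears the
  BH cutoff roughly half the time by construction, so "all five always
  missed" is not a property of this world.

## Known limitations

* No amplification-efficiency correction, standard curves, or multi-plate
  batch correction (out of scope by design).
* The t-approximation p-value for Spearman's rho is approximate at small n;
  an exact permutation option exists only in principle for n ≤ 10 via the
  oracle used in tests.
* No optimal-k selection; k is a user choice (default 3).
* The correlation screen's per-family BH is one defensible multiplicity
  scheme among several; the choice is recorded in the manifest.

## A minimal run

```{r, eval = FALSE}
library(qpcrstrat)
man <- run_pipeline(list(seed = 11L), "run1")
cat(readLines(file.path("run1", "report.md")), sep = "\n")
```
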