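# qpcrstrat

Differential expression and patient stratification for low-density qPCR
(TaqMan-card style) miRNA arrays in small clinical case/control cohorts.

## What problem it solves, and for whom

Clinical groups profiling circulating miRNAs on microfluidic qPCR cards get
back a matrix of cycle-threshold (CT) values — hundreds of assays by a few
dozen samples — riddled with "Undetermined" wells, plus a clinical sheet
(pain scores, comorbidities, medication flags) and often a multiplex
cytokine panel. `qpcrstrat` takes these three delimited tables through the
standard analysis chain:

1. **Censor** CT ≥ 32 cycles as undetected (values kept, masked; masks only
   grow) and **filter** assays by per-cohort detection rate;
2. **Quantile-normalize** detected CT values across samples
   (censoring-aware: undetected cells are excluded and never altered);
3. select a data-driven **endogenous control** — the 10 fully-detected
   assays with the lowest SD across samples — and compute
   ΔCT = CT − reference mean;
4. **test** patient-vs-control differences in ΔCT (two-tailed pooled-variance
   *t*-test, Benjamini–Hochberg adjustment) and report signed
   **2^-ΔΔCT fold changes** (ratios < 1 as negative reciprocals, so every
   magnitude is ≥ 1 and down-regulation is negative);
5. **stratify** patients by hierarchical clustering of per-sample log2
   relative expression over the significant assays (k = 3 by default),
   identify the patient-only "signature" group, and **re-test** it against
   all remaining samples;
6. run the same t/BH machinery on the **analyte panel**, and screen
   miRNA/analyte/clinical variable pairs with tie-corrected **Spearman**
   correlation (BH within namespace-pair family, kept at adjusted p < 0.01),
   exporting a circular-plot link table.

A seeded **synthetic cohort generator** with a recorded ground truth (41
patients / 20 controls, 758 assays, an 18-assay mostly-down signature carried
by 60% of patients, three elevated analytes of which two track the pain
score) makes the whole pipeline testable without any patient data. See
`vignettes/qpcrstrat-methods.Rmd` for the model, assumptions and design
choices.

## Worked example

```r
library(qpcrstrat)
man <- run_pipeline(list(seed = 11L), "run1")
cat(readLines("run1/report.md"), sep = "\n")
```

prints (abridged):

```
# qpcrstrat run report

Seed: 11
Assays: 758 total, 758 kept, 758 tested
Censored (undetected) cells after thresholding: 15
Reference set: 10 assays, SD range [0.0695, 0.0816]

## Differential expression: 25 significant assays (q < 0.05)

| assay | fold change | q |
|---|---|---|
| miR-0579 | 2.79 | 4.23e-05 |
| miR-0477 | -2.52 | 0.000171 |
...

## Stratification (k = 3)

| group | patients | controls | patient fraction |
|---|---|---|---|
| 1 (patient-only) | 25 | 0 | 61% |
| 2 | 16 | 19 | 39% |
| 3 | 0 | 1 | 0% |

Signature group: group 1, patient-only, 61% of all patients.

Subgroup-vs-rest comparison: 30 significant assays, 8 not significant in the all-patients comparison.

## Correlation screen: 5 of 14528 pairs kept (adjusted p < 0.01)

| var1 | var2 | rho | q |
|---|---|---|---|
| mirna:miR-0419 | clinical:headache | -0.677 | 0.00336 |
| ...
| clinical:pain_nrs | analyte:VEGF | 0.663 | 0.000207 |
| clinical:pain_nrs | analyte:IL1Ra | 0.581 | 0.00301 |
```

Reading this: the all-patients comparison finds the planted signature at
diluted (~2.5-fold) magnitudes because only the signature subgroup carries
it; clustering isolates that subgroup as a patient-only group holding ~60%
of patients; re-testing it against everyone else recovers the full planted
4-fold effects plus the half-shift subgroup-only markers; and the screen
keeps the planted pain–VEGF and pain–IL1Ra correlations (ρ ≈ 0.6).

Each stage is also a plain function (`read_ct_table`, `censor_undetected`,
`filter_assays`, `quantile_normalize`, `select_reference`,
`compute_delta_ct`, `differential_table`, `analyte_differential`,
`relative_expression`, `cluster_samples`, `group_composition`,
`subgroup_differential`, `correlation_screen`, `export_links`,
`simulate_cohort`, `simulate_null`) and a CLI verb
(`simulate | preprocess | diff | stratify | correlate | report | run-all`)
via `qpcrstrat_cli()` or the installed `scripts/qpcrstrat.R`. Every run
writes a JSON manifest with the effective thresholds and per-file MD5
digests; identical seed + config reproduce byte-identical outputs.

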