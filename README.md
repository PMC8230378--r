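# panelstrat

Biomarker panel triage for post-stroke infection risk.

Roughly one in five ischemic-stroke patients develops an infection
(pneumonia, urinary tract infection) during the first days of
hospitalization, and many patients receive prophylactic antibiotics they do
not need. `panelstrat` implements the analysis chain for the triage question
*which patients are at low enough risk that antibiotics can be withheld?*
using admission blood biomarkers — serum amyloid A (SAA, µg/mL), C-reactive
protein (CRP, µg/mL), procalcitonin (PCT, ng/mL), white blood cells (WBC,
10⁶/mm³), monocytes — and clinical parameters (NIHSS stroke-severity score,
admission temperature).

The package is aimed at biostatisticians reproducing or extending this kind
of two-stage (discovery → validation) biomarker study. Because patient-level
data from such studies are typically unavailable, a synthetic-cohort
generator calibrated from published per-class median (IQR) summary
statistics is a first-class, tested component.

## What it computes

* **Synthetic cohorts** — for each marker, a two-parameter distribution is
  fitted from the printed class-conditional `median (q1–q3)`:
  lognormal for right-skewed labs with `μ = ln(median)`,
  `σ = (ln q3 − ln q1) / (2 z₀.₇₅)`; normal for age and temperature;
  discretized lognormal (rounded, clamped to 0–42) for the NIHSS.
  Class counts are exact; markers are independent within class
  (`generate_cohort()`).
* **Demographics tables** — median/IQR with Mann–Whitney U (exact
  enumeration for small groups, tie-corrected normal approximation
  otherwise), Fisher exact and Pearson chi-squared for categorical rows
  (`cohort_summary_table()`).
* **Single-marker ROC** — empirical ROC with midpoint cutoffs, AUC equal to
  the tie-corrected concordance U/(n₁n₀), and the triage operating point:
  maximal specificity subject to SE ≥ 90% (`roc_curve()`,
  `cutoff_at_min_sensitivity()`).
* **Class-association rules** — supervised entropy binning, exhaustive
  conjunction enumeration, support / confidence / lift (lift =
  confidence ÷ class prevalence; 1 ⇔ independence), and a first-match rule
  classifier (`mine_rules()`).
* **CART decision tree** — Gini splits, minimum-terminal-node
  regularization, triage-safe tie-break (`grow_tree()`).
* **k-of-n threshold panels** — the core: an exhaustive search over marker
  subsets × per-marker threshold grids × vote counts k, declaring infection
  when ≥ k conditions such as `WBC > 10` hold, optimizing SP at fixed
  minimum SE or vice versa (`exhaustive_search()`, `refit_thresholds()`).
* **Study pipeline** — markers are selected on a small discovery subgroup
  (n = 40, 21 infected), thresholds re-estimated on a larger validation
  subgroup (n = 243, 39 infected), performance reported for both
  (`run_study()`, `compare_methods()`).

## Worked example

```r
library(panelstrat)

vali <- generate_cohort(validation_cohort_spec(), seed = 9)
res  <- refit_thresholds(c("saa", "wbc", "nihss"), vali,
                         mode = "high-se", s = 0.95)
print(res)
#> <panel_search_result> high-se, constraint 0.95
#>   NIHSS > 2.5 and SAA > 35.1473 and WBC > 6.29363 (infection when >= 2)
#> <perf_report> SE 97.4% SP 43.1% (TP 38 FP 116 TN 88 FN 1)
```

Read: on a 243-patient synthetic validation cohort, requiring at least 2 of
the 3 threshold votes flags 38 of the 39 infected patients (SE 97.4%) while
clearing 88 of the 204 non-infected patients (SP 43.1%) — i.e. roughly
four in ten patients could be spared antibiotics at the cost of missing one
infection in this draw. The full pipeline:

```r
report <- run_study(study_config(seed = 11))
compare_methods(report)[, c("method", "markers", "stability")]
#>              method       markers stability
#> 1     panel_high-sp crp,nihss,wbc 0.1649968
#> 2     decision_tree crp,nihss,wbc 0.2162278
#> 3     panel_high-se nihss,pct,saa 0.3199656
#> 4 association_rules crp,nihss,saa 0.5937922
```

`stability` is the total drift of the operating point between subgroups,
`|SE_d − SE_v| + |SP_d − SP_v|`; smaller transfers better.

A command-line front end wraps the same functions
(`inst/cli/panelstrat.R`):

```sh
Rscript inst/cli/panelstrat.R simulate --builtin validation --seed 7 --out cohort.csv
Rscript inst/cli/panelstrat.R panel cohort.csv --markers saa,wbc,nihss \
        --mode high-se --min-se 0.95 --out panel.json
```

## Limitations

Synthetic cohorts match printed class prevalences and per-marker
class-conditional medians/IQRs but draw markers independently within class;
between-marker correlations, longitudinal sampling, and any printed numbers
computed on the original (undeposited) patient data are out of reach. See
`vignettes/panel-triage-methods.Rmd` for the full methods discussion.
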