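---
title: "Methods: biomarker panels for triaging post-stroke infection risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker panels for triaging post-stroke infection risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelstrat)
```

## The problem

Stroke-associated infections (SAI) — pneumonia, urinary tract infections
and others appearing within the first five days of hospitalization —
drive much of the long-term morbidity after ischemic stroke, and the
countermeasure, early antibiotic therapy, is routinely over-applied.
The triage question this package addresses is the *negative* one: find, at
hospital admission, the patients at low enough infection risk that
antibiotics can be withheld. That framing dictates the operating regime
throughout: classifiers are tuned for very high sensitivity (missing an
infection is costly), and their value is measured by the specificity
achieved under that constraint — the fraction of non-infected patients the
rule can clear.

The measurements are admission values of serum amyloid A (SAA, µg/mL),
C-reactive protein (CRP, µg/mL), procalcitonin (PCT, ng/mL), white blood
cell count (WBC, 10⁶/mm³), monocytes (10⁶/mm³), the NIHSS stroke-severity
score (integer 0–42), admission temperature (°C), age, sex,
cardiovascular risk-factor flags and the TOAST stroke-etiology class. The
study design is two-stage: a small **discovery** subgroup (40 patients,
21 infected) selects a restrained set of markers; a larger **validation**
subgroup (243 patients, 39 infected) re-estimates cutoffs for exactly
those markers and provides the reported performance. Only marker
*identities* transfer between stages — with 40 patients, cutoffs do not
generalize, and the protocol acknowledges that explicitly.

## The synthetic-cohort generator

Patient-level data for studies of this kind are usually not deposited;
what is published is the demographics table: per class (infected /
non-infected), a `median (q1–q3)` triple per marker and counts for the
categorical variables. `generate_cohort()` turns those summaries into
patient-level tables so that every downstream method is executable and
testable.

**Distribution families.** The acute-phase labs (SAA, CRP, PCT, WBC,
monocytes) are modelled lognormal: they are positive and strongly
right-skewed (the published infected-class SAA triple 16.7 (4.7–89.2) has
its upper quartile five times the median). Age and temperature are
modelled normal (mean = median, sd = IQR/1.349). The NIHSS is an integer
score, modelled as a rounded lognormal clamped to [0, 42]. CRP has a
detection floor: draws below 3 µg/mL are reported as 3, reproducing the
published "3 (3–…)" pattern.

**Calibration.** A two-parameter lognormal is fitted per marker and class
as `μ = ln(median)`, `σ = (ln q3 − ln q1) / (2 z₀.₇₅)` with
`z₀.₇₅ = qnorm(0.75) ≈ 0.6745`. This matches the median exactly and the
IQR *width on the log scale* exactly. It cannot match both quartile
endpoints individually unless the triple is log-symmetric
(`median² = q1·q3`); for skewed triples the fitted quartiles are the
log-symmetric pair around the median with the correct ratio. With two free
parameters and three printed numbers this is the information-preserving
compromise; a three-parameter family would fit the endpoints but could not
be identified stably from a single printed triple.

**What the generator states.** Class counts are exact (19/21 discovery,
204/39 validation), not in expectation. Markers are drawn independently
within class: the published tables carry no correlation structure, so any
imposed correlation would be an invention. Categorical variables are
Bernoulli/multinomial draws at the published per-class proportions.
Cohorts are a pure function of (spec, seed).

**What a green test does not establish.** Because of within-class
independence, synthetic cohorts are *easier* than real ones for
multi-marker methods (real SAA, CRP and WBC are mutually correlated, so a
panel's effective dimensionality is lower in reality). Qualitative
reproductions — e.g. that a high-sensitivity SAA/WBC/NIHSS panel clears a
substantial fraction of non-infected patients — are meaningful; exact
published SE/SP values computed on the original patients are not
reproducible and are never asserted.

## Demographic statistics

`cohort_summary_table()` reproduces the demographics-table machinery:
median/IQR by the linear-interpolation quantile convention (the common
statistical default; the source convention is unstated, and all IQR-based
tests carry a 5% tolerance), Mann–Whitney U for numeric variables and
Fisher's exact or Pearson's chi-squared for categorical ones. The U test
enumerates all group assignments exactly for combined n ≤ 12 and otherwise
uses the normal approximation with tie correction and continuity
correction; the two-sided p doubles the smaller tail, capped at 1.
Fisher's two-sided p sums hypergeometric probabilities not exceeding the
observed table's. Chi-squared uses no Yates correction by default (the
checked published case rounds to the printed p either way); the package
records which test each row used, since the source does not state it per
row. These routines are written from first principles so the test suite
can use base R's `wilcox.test`, `fisher.test` and `chisq.test` as
independent oracles.

## ROC analysis

`roc_curve()` places one candidate cutoff at each midpoint between
adjacent distinct scores plus the two trivial endpoints, predicting
infected when the score is strictly above the cutoff (matching the strict
`WBC > 10` notation used in published panel rules, and producing
non-observed cutoff values like 2.6 or 6.4). The AUC is the trapezoidal
area, identically the concordance probability with ties counted ½ —
equivalently `U/(n₁·n₀)`; the package computes it both ways and the tests
assert the identity. `cutoff_at_min_sensitivity()` returns the attainable
point with maximal specificity among those with SE ≥ s, ties toward higher
SE and then toward the cutoff excluding more non-infected patients; when
the constraint is only met at the call-everyone-positive corner the point
is flagged low-information (the published tables print these rows as
"100% / 0% / –"). Marker directions default to higher-is-infected and are
configurable; the temperature row in the published validation table (cutoff
35.9 °C at SP 5%) shows why direction must stay configurable.

## Class-association rules

Antecedents are conjunctions of per-marker interval conditions with
closed-open intervals `[lo, hi)` partitioning the line. Discretization is
not stated in the source (its cutpoints like 6.5 or 8.65 are data-driven),
so the package uses recursive entropy-minimizing binary splits, stopping
at `max_bins` or when no split reduces class entropy, with an
equal-frequency fallback under degenerate supervision. Metrics follow the
standard definitions: support `n(A∧B)/N`, confidence `n(A∧B)/n(A)`, lift
`confidence / prevalence(B)` (1 ⇔ independence). Two consequences are
load-bearing for testing: every confidence-1 rule targeting the
non-infected class in a 19/21 cohort of 40 has lift 40/19 ≈ 2.1, and
targeting infected 40/21 ≈ 1.9 — arithmetic identities that hold whatever
the discretization. The published discovery-stage constraint ("support = 1
for the infectious group") is ambiguous; it is interpreted as retaining
confidence-1 rules on discovery, which is what the published discovery
rules all show. Classification is first-match over rules sorted by
(confidence, support, lift, antecedent string) descending, with the
training majority class as default; the source never states its conflict
resolution, so the order is a package decision made deterministic.

## Decision tree

A standard CART: Gini impurity (entropy available), exhaustive
marker × midpoint split search maximizing weighted impurity decrease, no
pruning — regularization is only by minimum terminal-node size, 4 on
discovery and 9 on validation, as in the source protocol. Leaf ties
predict non-infected: in this application a tie must not silently favor
the intervention class. Trees overfit by construction (the source makes
the same observation); they are included as a comparison method, not a
recommendation.

## The panel search

The core method is an exhaustive search over k-of-n threshold panels: a
panel is a set of conditions `marker > cutoff` (or `<`) plus a vote count
k, declaring infection when at least k conditions hold. The search
enumerates marker subsets (size ≤ 3 by default), per-marker cutoff grids
(midpoints between distinct values, thinned to a 25-point cap by even
quantile spacing retaining the extremes), and all k, optimizing SP at
SE ≥ s or SE at SP ≥ s, with s = 0.95 by default.

Implementation: instead of evaluating panels one by one, each patient is
reduced (per marker subset) to a vector of threshold ranks; the number of
patients with ≥ t satisfied conditions at *every* grid cell simultaneously
is a signed sum of reverse-cumulative rank histograms over condition
subsets (inclusion–exclusion over elementary symmetric counts). This makes
a 3-marker, 25³-cell, 243-patient search run in milliseconds; a naive
quadruple loop is retained in the test suite as the independent oracle and
equality is asserted on 230 randomized instances. Tie-breaks are fully
deterministic: higher secondary metric, fewer markers, lexicographic
marker names, smallest cutoff combination, smallest k. An infeasible
constraint returns the best-effort panel flagged infeasible rather than
erroring — with 40-patient discovery cohorts infeasibility is routine.

`refit_thresholds()` expresses the protocol's validation step: the marker
set is fixed, subset enumeration is disabled, but k stays free — the
published panels themselves change k between subgroups (≥2 on discovery,
≥1 on validation for the high-SE panel), confirming that k must be
re-estimated along with the cutoffs.

## Pipeline and method comparison

`run_study()` runs all three methods once on discovery (no resampling,
mirroring the original design), carries each method's selected markers to
validation, re-estimates there, and reports confusion counts for both
subgroups; every number in the report is recomputable from the recorded
seed and config, which a test verifies. Two pipeline constants are package
decisions: validation re-mining of association rules relaxes the
constraints to min support 0.02 and min confidence 0.5 (published
validation rules have supports down to 0.02 and confidences 0.5–0.96; the
discovery constraint would return nothing at prevalence 39/243), and the
rules method carries the top 3 markers ranked by the best (lift, support,
confidence) of any discovery rule, following the "highest lift" selection
narrative. `compare_methods()` ranks methods by stability,
`|SE_d − SE_v| + |SP_d − SP_v|` — the argument for the panel method in
this literature is precisely that its operating point transfers between
subgroups.

## Numerical choices and degenerate inputs

* Quantiles: type-7 linear interpolation throughout.
* Strict `>` at cutoffs everywhere (ROC, tree right branch, panel
  conditions); midpoint cutoff placement makes the choice of strictness
  immaterial for continuous draws but keeps tied values well-defined.
* Constant markers: empty threshold grid (skipped in search, error only if
  *all* grids are empty), single ROC curve with only trivial points,
  single bin, no tree split.
* Exact-tie handling: Mann–Whitney counts tied pairs ½; Fisher compares
  table probabilities with a 1e-7 relative slack (as `fisher.test` does);
  search feasibility uses a 1e-12 slack so that SE = s exactly is feasible.
* Degenerate lognormal (q1 = median = q3) is a flagged point mass.
* Seeds: cohorts restore the caller's RNG state; every stochastic test and
  the acceptance script derive sub-seeds below 2³¹.

## Known limitations

* Within-class marker independence (discussed above) — an optional
  correlation hook was considered and deliberately not defaulted on, since
  no published correlation matrix exists to calibrate it.
* Only admission values are generated; the original study also sampled
  days 1/3/5.
* The published figures' exact tree cutpoints are not reproducible from
  text and are not targets.
* Performance is resubstitution performance per subgroup, as in the
  source; no cross-validation is added, so absolute SE/SP values are
  optimistic in both stages.
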