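Package: panelstrat
Title: Biomarker Panel Triage for Post-Stroke Infection Risk
Version: 0.1.0
Authors@R:
    person("panelstrat", "developers", email = "panelstrat@example.org",
           role = c("aut", "cre"))
Description: Tools for stratifying ischemic-stroke patients at low risk of
    stroke-associated infection from admission biomarkers (serum amyloid A,
    C-reactive protein, procalcitonin, white blood cells, monocytes) and
    clinical scores (NIHSS, temperature). Implements a synthetic cohort
    generator calibrated from published median/IQR summary statistics,
    demographic-table statistics (Mann-Whitney U, Fisher exact, chi-squared),
    single-marker ROC analysis with sensitivity-constrained cutoff selection,
    class-association-rule mining (support/confidence/lift), CART-style
    decision trees, and an exhaustive k-of-n threshold-panel search that
    maximizes specificity at a fixed minimum sensitivity (or vice versa),
    together with a discovery-to-validation study pipeline and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
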