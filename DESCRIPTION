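Package: mrsurv
Title: One-Sample Mendelian Randomization for Cause-Specific Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Allele-score Mendelian randomization with survival outcomes:
    sex-stratified Wald-ratio estimation from a linear first stage and a
    left-truncated cause-specific Cox second stage, inverse-variance-weighted
    pooling, two-stage least-squares mediation through diabetes liability with
    a bias-corrected bootstrap proportion-mediated interval, summary-statistic
    sensitivity estimators (IVW, weighted median, MR-Egger), and non-linear
    Mendelian randomization by the residual and doubly ranked methods with
    age/sex negative-control diagnostics. Includes a synthetic admixed-cohort
    generator with known causal parameters (genetic scores, ancestry-linked
    allele frequencies, diabetes-induced reverse causality, competing causes
    of death) so every estimator can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
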