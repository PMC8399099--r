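Package: survscreen
Title: Genome-Wide Survival Biomarker Screening with Optimal Expression Cutpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for prognostic expression biomarkers in
    clinical cohorts. For each gene, patients are ranked by expression and a
    serial cut is slid across the 30th-70th percentile band; a two-group
    log-rank test is evaluated at every admissible cut and the minimum-p
    (optimal) cutpoint is selected, with a median-expression fallback.
    Gene-wise p values are corrected by Benjamini-Hochberg FDR and Bonferroni,
    and candidates must additionally show a hazard ratio of at least 1.8 (or
    at most 0.6) in both univariate and multivariate Cox proportional-hazards
    models adjusted for dichotomized clinical covariates, in both a discovery
    (optimal-cut) and a validation (median-cut) cohort with consistent effect
    direction. Includes a synthetic-cohort generator with planted threshold
    effects and known truth, so cutpoint recovery, minimum-p inflation, and
    consensus selection can be characterized without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
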