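Package: trialphen
Title: Phenotype Discovery and Treatment-Efficacy Gating for Clinical Trials
Version: 0.1.0
Authors@R:
    person("Trialphen", "Maintainers", email = "maintainers@trialphen.org",
           role = c("aut", "cre"))
Description: Identifies clinical phenotypes associated with treatment efficacy
    in randomized trials with a renal composite endpoint (MAKE90). Implements
    quartile-stratified risk-ratio variable screening with a monotone-run
    filter and slope ranking, preprocessing (missingness filtering, chained
    random-forest imputation, log/scale/center transforms, Bonferroni outlier
    removal), from-scratch consensus clustering for k-means and PAM with
    cluster-consensus scores and CDF-based k selection, a gated model search
    (consensus score > 0.90, per-phenotype log-rank efficacy), Table 1-style
    phenotype characterization, and a synthetic trial-cohort generator with
    planted phenotype structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    cluster,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
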