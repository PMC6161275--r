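Package: forpanel
Title: Functional-Overreaching Protein Biomarker Discovery from Dried Blood
    Spot Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for detecting functional-overreaching (FOR)
    protein biomarkers from longitudinal dried-blood-spot proteomics in a
    two-arm randomized crossover exercise study.  Covers study-design-aware
    synthetic data generation with planted acute/chronic/null protein
    response archetypes, top-3 peptide-to-protein rollup, empirical-Bayes
    batch correction, row-max normalization, technical-CV computation from
    pooled-QC injections, per-protein marginal (GEE-style) models of the
    time-by-condition interaction with cluster-robust standard errors and
    Tukey-adjusted pairwise contrasts, a CV-gated significance threshold,
    temporal-pattern classification into acute and chronic/FOR biomarker
    clusters, and a crossover-design statistical power simulation based on
    linear mixed models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
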