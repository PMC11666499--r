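Package: vusquant
Title: Points-Based Quantification of ACMG/AMP Variant Classifications
    with AlphaMissense Computational Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying germline variant classifications under the
    ACMG/AMP five-tier system using an integer point adaptation of the Bayesian
    classification framework. Assigned evidence codes are parsed against an
    extensible catalog (polarity, strength, strength modifiers, evidence type),
    converted to per-variant strength profiles and point totals, and mapped to
    tiers and VUS sub-bands. AlphaMissense pathogenicity scores are categorized
    by fixed thresholds and injected as supporting computational evidence (PP3
    or BP4) in augmentation and replacement experiments that tabulate
    quantification changes and tier transitions. Concordance between predictor
    categories and curated tiers is summarized as a 3x3 contingency table with
    two binary collapse schemes (sensitivity, specificity, PPV, NPV),
    comparison-group labels, and chi-square, rank-correlation and
    confidence-interval helpers. Deterministic fixtures expand published
    summary tables into per-variant cohorts, and a seeded generator simulates
    cohorts with realistic class proportions, score mixtures and
    evidence-combination frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
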