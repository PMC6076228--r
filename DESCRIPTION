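Package: mendeldx
Title: Ensemble Pathogenicity Scoring and Automated Mendelian Disease
    Diagnosis for Targeted Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for interpreting targeted next-generation sequencing
    panels in Mendelian disease diagnostics. Implements MPPS, a region-aware
    ensemble classifier that combines 17 deleteriousness predictors for
    nonsynonymous single-nucleotide variants using per-region predictor
    weights, trio selection, a conservation bonus and an iterative agreement
    protocol; and AADSM, an automated variant filtering, scoring and
    phenotype-driven disease ranking pipeline with JSON/HTML report
    generation. Includes benchmarking statistics (per-tool accuracy,
    prediction coverage, genotype concordance) and synthetic-data generators
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
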