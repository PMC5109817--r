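Package: germCore
Title: Core Collection Construction and Evaluation for Crop Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating core collections from large,
    structured crop germplasm collections genotyped with a small SNP panel and
    scored for qualitative and quantitative traits. Implements accession-level
    quality control (F1-hybrid and missingness filters), allele-frequency
    diversity statistics (observed and expected heterozygosity, polymorphic
    information content, Shannon index, Pielou evenness, per-cluster F_ST,
    distance-based AMOVA), Manhattan dissimilarity with neighbor-joining and
    UPGMA trees, principal coordinate analysis, Sturges-binned trait
    classification, a deterministic greedy maximum-coverage (advanced M
    strategy) core selector under five sampling strategies, the MD/CR/VD/VR
    plus Shannon/Pielou evaluation framework with multi-allelic hold-out
    marker validation, and a seeded Balding-Nichols germplasm simulator for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    phangorn,
    mclust,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
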