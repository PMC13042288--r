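Package: mamut
Title: Mutation-Accumulation Experiment Analysis: Filtering, Rates, Spectra and Genomic Context
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mutation-accumulation (MA) line panels from
    joint variant calls: GATK-style hard filtering with symmetric callable-site
    accounting, line-unique variant selection, clustering of nearby variants
    into multinucleotide and complex events, structural-variant and
    transposable-element call reconciliation, per-type mutation-rate estimation
    with bootstrap confidence intervals, mutation-spectrum statistics, and
    negative-binomial regression of per-window mutation counts on genomic
    covariates. Includes a synthetic MA-experiment generator with planted
    ground truth so every pipeline stage can be validated against a known
    answer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    glmmTMB,
    car,
    withr,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
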