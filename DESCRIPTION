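Package: adaptscape
Title: Multi-Scale Local Adaptation Analysis for Reciprocal Transplant and
    Provenance Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying adaptive divergence between closely
    related taxa and local adaptation among populations within a taxon from
    common-garden experiments.  Provides environmental principal-component
    niche comparison with a permutation null, generalized linear mixed model
    tests of taxon-by-garden interactions with local-vs-foreign and
    home-vs-away contrasts, a Weir-Cockerham F_ST estimator for biallelic
    diploid genotypes, provenance-trial regressions of population effects on
    geographic, environmental and genetic distance, and phenotypic
    selection-gradient analysis on principal-component scores with
    reconstitution of gradients back onto the measured traits.  Includes a
    synthetic-data generator that emulates a three-garden reciprocal
    transplant with structured genotypes so every stage of the pipeline can
    be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    car,
    multcomp,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
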