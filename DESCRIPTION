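Package: gutstress
Title: Gut Microbiome Composition and Acute Stress Reactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline linking gut microbiome composition to
    acute stress reactivity in humans. Processes 16S ASV count tables
    (rarefaction, rare-ASV filtering, genus aggregation, alpha diversity,
    Firmicutes/Bacteroidetes ratio), scores each sample's inferred capacity
    to produce the short-chain fatty acids butyrate and propionate from a
    genus-level producer annotation, derives per-participant salivary
    cortisol and subjective stress statistics (reactivity and recovery
    slopes, area under the curve with respect to ground and increase), and
    relates the two through Huber robust linear models fitted by
    iteratively reweighted least squares with variance-based R-squared
    measures, backward model reduction, and companion OLS diagnostics.
    Includes a Dirichlet-multinomial cohort simulator with planted effects
    so the whole analysis is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    MASS,
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
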