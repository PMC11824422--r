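Package: sfsdfe
Title: Demographic History and Fitness-Effect Inference from Folded Site-Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to infer piecewise-constant demographic histories and
    distributions of fitness effects (DFEs) of new mutations from folded
    site-frequency spectra (SFS), aimed at bacterial population samples
    assembled from per-host metagenomic calls. Includes quasi-phasing of
    dominant within-host strains, gene/site filters, hypergeometric SFS
    projection to a fixed sample size, a diffusion engine for expected
    spectra under selection and population-size change, multinomial and
    Poisson random-field maximum-likelihood fits, likelihood-ratio tests for
    DFE equality across datasets, Pagel's lambda estimation of phylogenetic
    signal in DFE summaries, and a synthetic-data module with independent
    Wright-Fisher and quadrature oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
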