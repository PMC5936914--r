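Package: paleomacro
Title: Macroecology and Trait Evolution from the Fossil Record
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for trait-based macroecological analysis of fossil
    vertebrate clades. Builds dietary ecomorphological indices
    (carnivory index from relative blade length, relative upper grinding
    area and jaw depth ratios via correlation-matrix PCA), estimates
    preservation-adjusted species durations with a birth-death MCMC
    under homogeneous Poisson fossil preservation, computes half-degree
    grid-cell occupancy and maximum locality coverage over time slices,
    measures phylogenetic signal (Pagel's lambda, Blomberg's K), fits
    PGLS and quantile regressions of duration on specialization, and
    selects among six trait-evolution models (BM, OU, ACDC, Trend,
    Drift, diversity-dependent) over a posterior sample of trees with
    AICc and Akaike weights. Includes a synthetic-data generator
    (birth-death trees with extinct tips, traits under each model,
    Poisson-preserved occurrences, extant morphometrics) so the whole
    pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme
Config/testthat/edition: 3
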