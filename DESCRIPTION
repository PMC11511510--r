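Package: metsel
Title: Multi-Environment Trial Analysis and Heritability-Weighted Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-year multi-environment field trials of
    quinoa (Chenopodium quinoa) accessions: simulation of plot-level phenotypes
    under a randomized complete block design with column effects, mixed-model
    fitting with fixed or all-random genotype, year and genotype-by-year terms,
    REML variance components, entry-mean broad-sense heritability, single-step
    max-|t| grand-mean and year-stability contrast tests, per-year Pearson
    correlation analysis, a heritability-weighted phenotypic selection index,
    and ranked selection reports for identifying accessions adapted to
    temperate regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    nlme,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
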