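Package: coralheat
Title: Coral Heat-Tolerance Phenotyping and Trait Trade-Off Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying coral colony heat tolerance from marine
    heatwave emulation experiments and testing for trade-offs against
    colony growth, fecundity, and symbiont community traits. Implements
    degree-heating-week (DHW) accumulation against an adjusted
    climatological baseline, ordinal bleaching-survival index (BSI)
    scoring of replicate fragments with procedural-control exclusion,
    alignment of fragment health onto a fixed DHW grid, size-corrected
    annual growth from repeat photogrammetry surveys, whole-colony
    fecundity scaling from polyp dissections, and exact conjugate
    Bayesian linear regressions reporting the posterior probability that
    a tolerance-trait slope is positive, both overall and as a
    progression across DHW levels. A synthetic-data generator emulates a
    full study (tank temperature loggers, fragment health surveys, 3D
    colony sizes, dissections, ITS2 symbiont profiles) with configurable
    tolerance-trait couplings, so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
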