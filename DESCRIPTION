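Package: richtrend
Title: Differential Richness Inference for Marker-Gene Surveys with an
    Abundance-Dependent Technical Trend Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring differences in microbial richness between
    sample groups from 16S rRNA (OTU/ASV) count tables while controlling for
    the spurious, abundance-dependent accumulation of false taxa. Estimates a
    within-genus taxa-accumulation trend by penalized smoothing splines (or
    loess), and uses it as a covariate in Poisson and negative-binomial
    regressions for genus-specific, sample-wide, and collection-level
    differential richness. Includes classical asymptotic richness estimators
    (Chao1, ACE) with standard errors, inverse-variance weighted
    meta-regression for comparison analyses, confounding and model-comparison
    diagnostics, and a synthetic-survey simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
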