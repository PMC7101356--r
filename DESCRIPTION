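Package: apcvar
Title: Cross-Site and Cross-Platform Variability Analysis of Automated
    Patch Clamp Potency Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the reproducibility of drug potency (IC50)
    measurements obtained on automated patch clamp (APC) platforms across
    multiple laboratories. Implements well-level quality control and
    leak-corrected percent-inhibition computation, constrained
    four-parameter-logistic (Hill) concentration-response fitting with a
    no-fit rule for non-blocking drugs, log-scale IC50 summaries, one-way
    between/within-platform variance components on unbalanced designs,
    repeatability coefficients, and Bland-Altman limits-of-agreement
    analysis with a 3-fold acceptance criterion. Includes a hierarchical
    synthetic multi-site study generator emulating a 12-drug, 4-current,
    17-site ring trial for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
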