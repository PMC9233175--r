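Package: cibrood
Title: Quantifying Wolbachia-Induced Cytoplasmic Incompatibility from Brood Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the strength and phenotype of Wolbachia-induced
    cytoplasmic incompatibility (CI) in haplodiploid arthropods from replicated
    brood counts. Provides a full-diallel cross design builder, a generative
    simulator of haplodiploid CI broods with known ground truth, Bayesian
    binomial regression with logit link and day random intercepts (via JAGS),
    corrected CI indexes (CI_corr, MD_corr, FM_corr) propagated through
    posterior draws, WAIC model comparison with finite-population variance
    decomposition of model terms, and an ordered two-component binomial
    mixture model for Mendelian segregation analysis of maternal CI modifiers
    in backcross designs. All user-facing functions take and return tidy data
    frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
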