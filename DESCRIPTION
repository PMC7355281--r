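Package: twinconcord
Title: Quantitative Concordance and Discordance Analysis for Monozygotic Twin Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of concordance and discordance in
    monozygotic (MZ) twin pairs assessed on continuous trait scales such as the
    Social Responsiveness Scale (SRS-2). Provides pairwise and probandwise
    concordance statistics, a quantitative discordance classifier (difference
    of at least k clinical standard deviations and twins on opposite sides of
    a clinical threshold), a correction procedure for parent-reported
    discordance, twin-difference and twin-correlation summaries, a calibrated
    synthetic twin-cohort generator with a severity-dependent discordance
    variance regime, and a Gaussian-copula resampling simulation (with an
    analytic truncated bivariate-normal oracle) that quantifies how much
    restriction of range above a clinical cutoff attenuates the expected
    twin-twin correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    jsonlite,
    rlang,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
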