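Package: lifedist
Title: Distribution Analysis of Lifespan Cohort Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the distribution of lifespan as a trait in
    fully observed mortality cohorts (e.g. Drosophila survival assays).
    Converts deaths-per-day records to lifespan series, bins lifespans into
    day intervals (fixed width or Sturges' rule, with zero-interval trimming
    and interval-count equalization between paired cohorts), assesses
    normality of the intervalized frequency series with a hybrid
    Shapiro-Wilk test (original small-sample W coefficients combined with
    Royston's p-value transformation) and with one-sample Kolmogorov-Smirnov
    variants (Kolmogorov, Marsaglia, Lilliefors), compares cohorts with a
    two-sample Kolmogorov-Smirnov test on product-limit survival curves,
    overlays closed-form normal and beta-distribution curves on frequency
    histograms, and simulates the operating characteristics of the hybrid
    test on deterministic ideal normal mortality series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse
Config/testthat/edition: 3
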