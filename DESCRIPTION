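Package: ringsync
Title: Tree-Ring Network Synchrony and Climate-Growth Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds detrended tree-ring site chronologies from Tucson-format
    ring-width files (negative-exponential, straight-line or cutoff-spline
    detrending, Tukey biweight robust mean, rbar/EPS/SSS reliability
    diagnostics with SSS truncation), quantifies network-wide growth
    synchrony by running-window principal component analysis and extreme
    ring frequency, screens monthly climate predictors over the 17-month
    dendroclimatic year with correlation functions, 30-year moving
    correlations and a Monte Carlo (Gershunov-style) stability test,
    partitions site responses under contrasting winter-temperature regimes
    by fuzzy C-means clustering with pseudo-F diagnostics, and probes
    nonlinearity with ensemble empirical mode decomposition trends and a
    small feed-forward neural network response surface with breakpoint
    detection. A seeded synthetic-data module generates ring-width networks
    and monthly climate with known ground truth so every stage has a
    parameter-recovery test.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    nnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
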