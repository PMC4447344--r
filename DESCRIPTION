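Package: mcdspace
Title: Probability-Based Design Spaces for Designed Process Experiments by
    Monte Carlo Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quadratic response-surface modelling of designed process
    experiments with p-value based bidirectional stepwise term selection,
    Monte Carlo regeneration of response data under configurable noise
    distributions (normal, lognormal, square-root-normal,
    reciprocal-normal), per-simulation refitting, and grid probability maps
    from which a probability-based design space (joint probability of
    meeting all critical-quality-attribute limits above a threshold) and
    its size and stability metrics are extracted.  Ships the 15-run,
    three-factor Danhong injection extraction study as a fully worked
    example data set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
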