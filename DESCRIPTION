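Package: nestcrw
Title: Nested Switching Correlated Random Walk Models for Telemetry and
    Dive Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a two-layer hidden-state correlated random walk to
    satellite telemetry and transmitted dive summaries. A top-layer
    Markov chain switches movement between traveling and
    area-restricted search on a regular six-hour grid, with Argos
    location error handled through class-specific measurement variances
    and within-interval linear interpolation; a nested sub-chain inside
    area-restricted search classifies individual dives as foraging or
    resting from a truncated-normal depth mixture. Includes a
    generative simulator for both data streams, the standard filtering
    and regularization chain for Argos tracks and dive records,
    Metropolis-within-Gibbs posterior sampling with forward
    filtering-backward sampling of the discrete states, Gelman-Rubin
    convergence diagnostics, posterior state decoding, and behavioral
    summaries (time-in-state proportions, per-state depth
    distributions, seasonal and diel frequency profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
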