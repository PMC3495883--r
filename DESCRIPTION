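Package: webrds
Title: Simulation, Cleaning and Estimation for Web-Based Respondent-Driven Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying web-based respondent-driven sampling (webRDS) of
    hidden populations. Simulates chain-referral recruitment with electronic
    coupons on synthetic social networks with degree heterogeneity, attribute
    homophily and geographic structure; fabricates survey submission tables with
    realistic invalid records (underage, duplicated contact tokens, shared IP
    addresses, implausibly fast completions); flags invalid submissions and builds
    progressively stricter inclusion groups for sensitivity analysis; estimates
    population proportions and means with the inverse-degree-weighted RDS-II
    (Volz-Heckathorn) estimator including harmonic-mean network-size imputation;
    and runs Markov-chain equilibrium diagnostics (recruitment transition
    matrices, stationary compositions, waves to equilibrium, running-composition
    and last-k stability checks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
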