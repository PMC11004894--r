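Package: yieldbayes
Title: Bayesian Comparison of Yield-Monitor Data from Treated and Control Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for on-farm experimentation with combine yield-monitor
    data. Simulates per-polygon dry-yield measurements for test (green
    manure) and control fields with spatially correlated fertility
    variation, cleans them with a 3-sigma outlier rule, balances the two
    groups by per-field stratified random sampling, estimates each group's
    yield mean and standard deviation by random-walk Metropolis MCMC under
    a normal likelihood, and summarises the treatment effect through the
    contrast (posterior difference) distribution, its highest density
    interval, and the posterior probability that a treated measurement
    exceeds a control one.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
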