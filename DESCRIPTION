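Package: uhcd
Title: District-Level Universal Health Coverage Index Construction and
    Analysis
Version: 1.0.0
Authors@R:
    person("UHC Metrics", "Contributors", role = c("aut", "cre"),
           email = "uhcd@example.org")
Description: Builds a district-level universal health coverage index
    (UHC_d) by hierarchical geometric-mean aggregation of 24 tracer
    indicators grouped into 17 tracer areas and 5 tracer domains
    (reproductive, maternal, newborn and child health; infectious
    diseases; noncommunicable diseases; service capacity and access;
    financial risk protection).  Includes equity analysis via subgroup
    geometric-mean ratios, Wagstaff-style concentration and achievement
    indices, between/within-state variance decomposition by restricted
    maximum likelihood with a method-of-moments cross-check, hot-deck,
    regression and redistricting imputation, a rank-stability sensitivity
    battery, and a synthetic-data generator that emulates a 687-district,
    33-state survey table for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
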