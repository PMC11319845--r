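Package: mitefear
Title: Stage-Structured Simulation of Consumptive and Nonconsumptive
    Effects of an Ectoparasitic Mite on Fly Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Daily stage-structured stochastic simulation of Drosophila
    nigrospiracula populations exposed to the ectoparasitic mite Macrocheles
    subbadius.  Infection (consumptive effects) and parasite-presence costs
    (nonconsumptive "fear" effects) on eggs, larvae/pupae and adults are
    encoded as life-stage effect sizes and converted into daily vital rates;
    six exposure scenarios are simulated as replicate ensembles with
    reproducible seeding.  Includes calibration of the daily infection
    probability to a target lifetime prevalence by stochastic bisection, a
    deterministic daily projection matrix with growth rate and elasticity
    analysis, ensemble summaries (percent change versus the parasite-free
    baseline, realized prevalence), trajectory figures, and a YAML-configured
    end-to-end experiment driver with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
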