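Package: brcascreen
Title: Cost-Effectiveness Modelling of BRCA1/2 Carrier Identification Strategies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort decision model comparing population strategies for
    identifying BRCA1/2 pathogenic-variant carriers among 18-year-old women:
    clinical criteria and family history alone, or combined with a
    radiogenomic ultrasound classifier at two performance levels. The model
    propagates eligibility for genetic testing, carrier detection,
    risk-reducing surgery uptake, stratum-specific cancer incidence,
    healthy-life-years lost, and direct health-service costs over a 62-year
    cycle and three generations with cascade testing, and derives incremental
    cost-effectiveness ratios (ICERs) under central, best-case and worst-case
    parameter scenarios. Includes an individual-level Monte Carlo
    microsimulation whose expectations validate the deterministic cohort
    engine, YAML parameter configuration, and report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
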