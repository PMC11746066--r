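Package: tkicea
Title: Cost-Effectiveness of First-Line Tyrosine Kinase Inhibitor
    Strategies in Chronic Myeloid Leukemia
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Markov cohort state-transition model for the 20-year
    cost-effectiveness of first-line tyrosine kinase inhibitor (TKI)
    treatment strategies (imatinib, nilotinib, dasatinib) in chronic
    myeloid leukemia from a South African public-payer perspective.
    Provides a packaged base-case parameterization, a cohort trace engine
    with half-cycle correction and discounting, incremental
    cost-effectiveness analysis (ICER, net monetary benefit,
    willingness-to-pay thresholds), one-way deterministic sensitivity
    analysis with tornado ordering, probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves and confidence ellipses,
    an individual-level microsimulation used to verify the cohort engine,
    and a generator of random valid model specifications for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
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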