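Package: txace
Title: Lifetime Cost-Effectiveness Model of Tranexamic Acid for Acute
    Gastrointestinal Bleeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-state (alive/dead) Markov cohort model estimating the
    lifetime costs, life years and quality-adjusted life years of treating
    acute gastrointestinal bleeding with tranexamic acid versus usual care
    alone, from a UK health-service perspective. Trial-period mortality uses
    a daily death curve over 28 days with the treatment effect applied as a
    risk ratio on the cumulative risk; longer-term survival extrapolates a
    general-population life table with standardised-mortality-ratio hazard
    adjustment. Includes distribution fitting from published summaries,
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves and plane quadrant shares, a deterministic one-way scenario
    runner, and a synthetic patient-level trial generator with matching
    parameter estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
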