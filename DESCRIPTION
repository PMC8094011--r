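Package: nsclcCEA
Title: Markov Cohort Cost-Effectiveness Model for First-Line
    Immunotherapy in Advanced NSCLC
Version: 1.0.0
Authors@R: person("Model", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A four-state Markov cohort model comparing first-line
    nivolumab-ipilimumab combination therapy against platinum-doublet
    chemotherapy in advanced non-small cell lung cancer. Derives monthly
    transition probabilities from digitized overall-survival and
    progression-free-survival curves via a cause-specific hazard split,
    extrapolates beyond trial follow-up under either a conditional-survival
    or a cure (life-table) assumption, and accrues discounted costs and
    quality-adjusted life-years under a healthcare or societal perspective.
    Provides incremental cost-effectiveness ratios, one-way deterministic
    sensitivity analyses, bisection threshold searches for drug price and
    treatment duration, named scenario analyses, probabilistic sensitivity
    analysis with gamma/beta parameter distributions, cost-effectiveness
    acceptability curves, and a synthetic trial-data generator so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
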