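Package: lynchcea
Title: Cost-Utility Modelling of Reflex Testing for Lynch Syndrome in
    Early-Onset Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Analytics", "Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-component decision-analytic model for evaluating
    strategies to identify Lynch syndrome among newly diagnosed
    early-onset colorectal cancer patients and their relatives.  A
    diagnostic decision tree evaluates nine test cascades (microsatellite
    instability, immunohistochemistry, BRAF V600E or MLH1 promoter
    hypermethylation, diagnostic mutation testing and family-history
    criteria), cascading confirmed mutations to relatives.  An individual
    patient simulation accrues lifetime discounted costs and
    quality-adjusted life years under biennial colonoscopic surveillance
    and prophylactic gynaecological surgery.  The package performs the
    full incremental cost-utility analysis (ICERs, dominance and extended
    dominance, net health benefit), scenario and one-way sensitivity
    analyses, and colonoscopy service projections, driven by a declarative
    parameter set with a synthetic-parameter generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
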