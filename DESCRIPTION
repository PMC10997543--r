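Package: ihmvar
Title: Variance Partitioning and Reliability-Adjusted Profiling of In-Hospital
    Mortality After Complex Cancer Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential multilevel random-intercept logistic models that
    partition variation in in-hospital mortality after complex cancer surgery
    (esophagectomy, pneumonectomy, pancreatectomy, proctectomy) into shares
    attributable to patient characteristics, hospital case volume, hospital
    structural characteristics, and social determinants of health, on the
    latent logistic scale (residual variance pi^2/3). Includes empirical-Bayes
    reliability adjustment of hospital mortality rates with tertile grouping
    and funnel-plot control limits, Leapfrog volume classification, cohort
    descriptive machinery, and a calibrated synthetic discharge-cohort
    generator with known ground truth so every stage is testable without
    access-restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
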