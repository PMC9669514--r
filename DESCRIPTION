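Package: condplan
Title: Sequential Meta-Analysis and Conditional Planning of Sham-Controlled Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evidence-based planning of randomized controlled trials
    with sham (placebo-procedure) control arms. Implements two-sample
    difference-in-means power and sample-size calculation (normal approximation
    and exact noncentral-t), inverse-variance fixed-effect and
    DerSimonian-Laird random-effects meta-analysis of mean differences,
    cumulative meta-analysis in publication order, alpha-spending sequential
    monitoring with numerically integrated group-sequential boundaries,
    conditional-power sample-size planning for a next trial given the
    accumulated meta-analytic evidence, and a generator of synthetic
    sequential trial datasets for simulation studies. Ships the summary data
    of six sham-controlled renal sympathetic denervation trials as a worked
    example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
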