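Package: sexlability
Title: Sex-Expression Lability Analysis for Longitudinal Plant Censuses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing yearly sex-expression censuses of plants with
    labile gender, built around the subdioecious six-category system
    (female, male, and four hermaphrodite classes). Estimates discrete-time
    Markov transition matrices between sexual states, computes stationary
    (steady-state) sex ratios with bootstrap percentile confidence intervals
    and tests them against a uniform null, classifies individual trajectories
    into canonical sex-change patterns (constant, unidirectional,
    bidirectional), and provides the accompanying frequentist toolbox:
    G likelihood-ratio tests for sex-ratio heterogeneity, Kruskal-Wallis
    tests, and logistic random-intercept models of sex-change occurrence with
    backward AIC selection. Includes a synthetic census generator so the whole
    pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
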