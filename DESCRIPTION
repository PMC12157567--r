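Package: typicality
Title: Typicality Bounds and Majority-Rule Error Rates for Small-Sample
    Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Inference about the population typicality (prevalence) of a
    qualitative outcome from per-subject test results in small samples.
    Provides exact equal-tailed binomial confidence bounds for the
    per-subject significance rate, their transformation to lower bounds on
    typicality given per-subject false-positive rate and sensitivity,
    analytic correct/incorrect/inconclusive rates of N-out-of-M majority
    decision rules with threshold solving, one-sided binomial-tail tests of
    the majority-null (typicality < 0.5) and global-null (typicality = 0)
    hypotheses, a seeded Monte Carlo verifier for every analytic quantity,
    and report emitters producing the reference tables and figure data
    series as CSV or JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
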