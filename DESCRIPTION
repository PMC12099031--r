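Package: iccagree
Title: Confidence Intervals and Sample Size Planning for the Intraclass
    Correlation Coefficient for Agreement
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation, confidence intervals and sample-size determination
    for the intraclass correlation coefficient (ICC) for agreement under the
    balanced two-way random-effects ANOVA model (n participants each rated
    once by the same k raters).  Implements seven interval constructions
    (delta method on the log scale and in matrix form, two modified
    large-sample intervals, the generalized confidence interval, and
    F- and beta-based variance-partitioning intervals), a Monte Carlo
    harness to evaluate their coverage and width, and two sample-size
    procedures driven by the expected confidence-interval width: a purely
    simulation-based bisection search and a variance-reduced procedure
    using dependent conditioning, inverse Rao-Blackwellization and control
    variates, together with asymptotic-width feasibility checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
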