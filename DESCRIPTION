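Package: danpselect
Title: DEMATEL, ANP and Hybrid DEMATEL-ANP Decision Analysis for
    Project Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-criteria decision analysis for prioritising improvement
    projects (e.g. six-sigma project portfolios in healthcare) over a
    decision network of strategies, criteria clusters, sub-criteria and
    alternatives. Implements DEMATEL (normalised direct-relation and
    total-relation matrices, prominence and relation indices,
    dispatcher/receiver classification, inner-dependence matrices), the
    Analytic Network Process (reciprocal pairwise-comparison matrices on
    the Saaty scale, principal-eigenvector priorities by power iteration,
    consistency ratios, raw/weighted/limit supermatrices, block
    normalisation and global weights), and the hybrid DEMATEL-ANP (DANP)
    coupling in which DEMATEL inner-dependence matrices parameterise the
    ANP supermatrix. Includes a robustness harness (rank stability under
    duplicated alternatives or sub-criteria, judgment-count accounting),
    group-judgment aggregation, a synthetic decision-model generator with
    known ground truth, and tidy tibble outputs with tidy(), glance() and
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
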