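Package: refstab
Title: Reference-Gene Stability Analysis for qPCR Ct Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates candidate reference (housekeeping) genes for qPCR
    normalization from quantification-cycle (Ct) matrices. Implements four
    independent stability statistics - the comparative delta-Ct method,
    geNorm pairwise-variation M-values with iterative exclusion and the
    V(n/n+1) statistic, BestKeeper descriptive dispersion and index
    correlation, and the NormFinder model-based variance decomposition with
    grouped and ungrouped stability values - together with a comprehensive
    rank aggregation by geometric mean of per-method ranks. Also provides
    cohort quality-control filtering, 2^-ddCt relative quantification with
    nonparametric group comparison to quantify how reference choice alters
    biological conclusions, and a seeded synthetic Ct-cohort generator with
    recorded ground truth for benchmarking.
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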