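Package: swpeval
Title: Process Evaluation for Stepped-Wedge Cluster-Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative process-evaluation toolkit for hybrid
    effectiveness-implementation stepped-wedge trials. Computes pre/post
    process effect measures (odds ratios, proportion ratios) with
    confidence intervals, builds a rank-based composite implementation
    strength score across fidelity, reach and adoption domains, pools
    site-level effects by DerSimonian-Laird random-effects meta-analysis,
    regresses site effects on implementation scores by method-of-moments
    meta-regression, and estimates site-level intervention effects from
    cluster-period event counts by independence-working logistic
    regression with cluster-robust sandwich variance. Includes a
    synthetic stepped-wedge trial generator so the whole analysis chain
    can be exercised and validated by parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
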