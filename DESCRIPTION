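Package: clocklight
Title: Circadian and Light-Responsive Gene Expression Analysis for
    Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the interaction between circadian
    regulation and fluctuating light in Synechococcus elongatus.
    Implements median/ORF-length normalization of expression time
    courses, single-component cosinor rhythm detection with
    dawn/dusk/non-circadian classification, correlation-distance
    k-means clustering of dusk genes, ChIP enrichment peak calling with
    strand-aware promoter assignment, and phenomenological Hill
    AND-gate ODE models of dusk-cluster expression driven by
    phosphorylated RpaA and RpaB, fitted by multi-start bounded
    nonlinear least squares and compared by AIC. A seeded synthetic
    data generator emulates diel light profiles, regulator
    phosphorylation dynamics, cluster-structured expression, and ChIP
    signal tracks with planted peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
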