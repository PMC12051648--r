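Package: cosicc
Title: Knockout Effects in Chimera Single-Cell Experiments: Differential
    Abundance, Developmental Kinetics, and Interaction Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical comparison of marker-positive (injected, e.g.
    tdTomato+) against marker-negative (host) cells in chimeric embryo
    single-cell RNA-seq experiments, always contrasted with an external
    wild-type control experiment. Provides group-level and lineage-trajectory
    differential abundance testing with correction of the fixed-quota sampling
    bias, fate-matrix propagation from stage-to-stage transition matrices,
    detection of developmental delay or acceleration along pseudotime via
    Wilcoxon location-shift confidence intervals, per-cell-type interaction
    differential expression with a negative-binomial mixed-effects model
    (pool-level random intercept), gene-set signature scoring, half-sample
    sub-clustering with classifier label transfer, and a synthetic chimera
    data generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    MASS,
    glmmTMB,
    igraph,
    e1071,
    mclust,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
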