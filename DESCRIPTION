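Package: livage
Title: Single-Nucleus Liver Aging Analysis Toolkit
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable, tested pipeline for single-nucleus RNA-seq aging
    analyses of the liver: quality-control filtering and log1p-CP10K
    normalization, transcriptional-noise quantification via equal-UMI
    down-sampling and distance-to-centroid, binned-control gene-set and
    cell-identity scoring, marker-score hepatocyte zonation assignment,
    Wilcoxon rank-sum aging DEG calling with fold-change conventions,
    zonation overlap modules, ligand-receptor interaction scoring with a
    cell-type-label permutation null and young/aged differential networks,
    Cohen's kappa term-similarity graphs, and a negative-binomial synthetic
    data generator with known ground truth so every stage is verifiable
    without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
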