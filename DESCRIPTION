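Package: synProfiler
Title: Deep Phenotypic Profiling of Fluorescent Synaptic Puncta
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative, population-level phenotyping of
    fluorescently labelled synaptic puncta along straightened axon segments.
    Simulates ground-truthed axon images and animal populations, detects and
    segments puncta (multi-scale blob candidates pruned by a support vector
    machine), converts each animal's puncta into a fixed 76-feature phenotypic
    profile, fits pairwise mutant-versus-wild-type stepwise logistic regression
    models with deviance-based forward-backward feature selection, evaluates
    them by cross-validated ROC/AUC and sensitivity/specificity against
    best-single-feature baselines, and relates genotypes through cross-model
    probability matrices, correlation-weighted phenotype distances and
    hierarchical clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    EBImage,
    tiff,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
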