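Package: NeScape
Title: Demographic Resilience from Sequential-Coalescent Ne Reconstructions
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing and comparative analysis of piecewise effective
    population size (Ne) reconstructions produced by sequentially Markovian
    coalescent tools. Harmonizes trajectories across species, populations and
    bootstrap replicates onto a common logarithmic time grid, applies
    quantile-based reliability filters, summarizes Ne per climatic epoch by
    weighted harmonic means, estimates population split times from relative
    cross-coalescence rates, computes windowed nucleotide diversity,
    Weir-Cockerham FST and dxy from genotypes, and relates Ne trajectories to
    sea-level and host-specialisation covariates with mixed models and a
    permutation functional ANOVA. A synthetic-data module generates all inputs
    with known parameters so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    lme4,
    lmerTest,
    vcfR,
    geosphere,
    yaml
Suggests:
    glmmTMB,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
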