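Package: StoichResist
Title: Soil C:N:P Stoichiometry and the Resistance of C, N and P Cycling
    Microbial Populations to Global Change
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how soil carbon:nitrogen:phosphorus
    stoichiometry and climate (mean annual temperature and precipitation)
    govern the abundance of C, N and P cycling microbial populations, assayed
    by functional-gene qPCR, and their resistance to simulated global-change
    stressors (drying-wetting cycles, warming, nitrogen deposition). Provides
    the Orwin-Wardle resistance index, functional-group abundance
    normalization, Hellinger-transform variance partitioning with permutation
    tests, random-forest predictor importance with response-permutation
    significance, recursive path-model (SEM) fitting with chi-square, RMSEA
    and AIC fit evaluation and backward pruning, qPCR standard-curve
    utilities, and a seeded multi-site microcosm simulator so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
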