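Package: dielcycle
Title: Detection and Regulatory Analysis of Diel Cyclic Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cyclically expressed genes in short, evenly sampled
    gene-expression time courses using a discrete-Fourier-transform cyclic
    score with Welch segment averaging and a permutation null, estimates
    period, amplitude and phase, groups cycling genes into phase and
    expression clusters, tests functional and promoter-motif enrichment per
    phase, models the evolution of cycling state between duplicate genes
    with a three-state difference-equation model, compares cycling between
    ortholog pairs of two species, and predicts expression phase from
    promoter motif presence with naive and max-margin classifiers. Includes
    a synthetic-data generator emulating a two-day, 3-hour-resolution diel
    sampling design so the full pipeline can be exercised against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
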