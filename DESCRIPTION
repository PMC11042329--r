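Package: sedseq
Title: Transcriptome-Scale Analysis of mRNA Condensation by Sedimentation
    Fractionation Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying stress-induced mRNP condensation in budding
    yeast from sedimentation fractionation RNA-seq (Sed-seq). Implements
    Bayesian estimation of the proportion of each transcript in the supernatant
    (pSup) from Total/Supernatant/Pellet count data via per-experiment mixing
    ratios, length-controlled condensation and escape scores (lopSup, deltaSed,
    eSed, rSed/sedScore), a biophysical mass-based sedimentation model with
    nested-model F-tests and effective-size arithmetic, spike-in-normalized
    ribosome occupancy and association metrics, and a per-cell smFISH
    colocalization z-score. A synthetic-data module generates fraction counts,
    polysome tables, qPCR plates and two-channel image fields with the
    statistical structure the analysis assumes, so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
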