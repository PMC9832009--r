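Package: astDNB
Title: Dynamic Network Biomarker Detection of the Adeno-to-Squamous
    Transdifferentiation Tipping Point
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for locating critical transitions (tipping points) in
    temporal bulk transcriptomic series using the dynamic network biomarker
    (DNB) framework, with application to adeno-to-squamous
    transdifferentiation (AST) of lung tumors. Provides RLE (median-of-ratios)
    normalization to log2 reads-per-million, per-timepoint Pearson
    correlation networks, deterministic hierarchical module detection, the
    composite criticality index CI = (PCCi/PCCo) * SDi, tipping-point
    identification with a sliding-window variant for sparse replication, PCA
    trajectory and per-timepoint dispersion analysis, gene-set z-score
    signatures, ADC/SCC lineage scores and the AST score, Fisher-exact
    transcription-factor target overlap tests with a mutual-suppression
    ("Yin-Yang") network builder, cohort incidence summaries, and a synthetic
    time-course generator that plants a DNB-style critical transition for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, TimeCourse, Network, GeneExpression,
    DifferentialExpression
RoxygenNote: 7.3.3
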