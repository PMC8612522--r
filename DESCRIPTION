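Package: tempocode
Title: Temporal Transcription-Factor Code Analysis with Synthetic Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the temporal transcription-factor code of
    developing neurons: generation of synthetic fluorescence section images,
    single-cell count matrices and flow-cytometry event tables with known
    ground truth; EdU-birthdating image quantification (adaptive-threshold
    watershed segmentation, per-section intensity normalisation, outlier
    trimming, positivity calling and EdU-TF colocalization); flow-cytometry
    gating with per-sample dynamic thresholds; temporal-marker discovery by
    stage-wise rank-sum differential expression with a cross-domain
    consistency filter; in-vivo/in-vitro expression-dynamics comparison by
    Pearson-correlation partitioning; and pseudotime binning with an
    expression-wave order statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
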