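Package: iegkinetics
Title: Kinetic Modelling of Immediate-Early-Gene Fluorescence Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and segregates neuronal ensembles from in vivo
    immediate-early-gene (IEG) fluorescence time courses. Models cfos
    promoter driven fluorophore expression as consecutive first-order
    kinetics (mRNA -> protein -> degraded protein), fits single- and
    double-activation profiles to per-nucleus traces by
    Levenberg-Marquardt least squares, selects models by the Akaike
    Information Criterion, classifies cells into context-representation
    categories across two imaging sessions, and summarises populations
    (rate-constant histograms with Gaussian modality fits, ensemble
    overlap, amplitude-binned reactivation probability). Includes a
    synthetic-data generator for traces and 4D image stacks with known
    ground truth, and ROI-based trace extraction with re-centering and
    Gaussian z-profile peak estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
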