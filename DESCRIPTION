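Package: gastrucomp
Title: Quantitative Image Analysis of Cell Competition in Mosaic Gastruloids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cell competition between fluorescently
    labelled clones in 3D gastruloids from confocal image stacks. Implements
    validation of 3D segmented nuclei with data-driven size thresholds,
    relative radial position, k-nearest-neighbour local density and
    neighbourhood composition, spectral spillover compensation with per-plane
    baselines and per-plane Tukey-fence gating of extreme marker levels,
    nuclear-to-cytoplasmic ratio quantification, three-stage apoptosis
    classification, per-gastruloid competition effect sizes and washout
    dilution arithmetic, whole-gastruloid morphometry via maximum-entropy
    thresholding, and transcriptome staging against timed references. A
    synthetic mosaic-gastruloid generator with known ground truth makes every
    stage testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    DESeq2,
    knitr
Config/testthat/edition: 3
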