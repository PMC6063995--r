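Package: emrecon
Title: Serial-Section Electron Microscopy Volume Reconstruction and Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for serial-section transmission electron
    microscopy (ssTEM) volume reconstruction and its quality control. Stitches
    overlapping camera tiles into section montages by normalized FFT
    cross-correlation, deformable triangle-mesh refinement, RANSAC point-match
    filtering and a regularized sparse affine solve; orders shuffled section
    series by shortest-path search over feature-correspondence counts; aligns
    sections into a volume by montage-scape matching, block matching and a
    global regularized solve; removes tile seams by gradient-domain (screened
    Poisson) processing and matches low-frequency intensity across sections;
    estimates image signal-to-noise ratio by a feature-based method and a
    cell-membrane method with voxel-size normalization; classifies degraded
    tiles and missing sections; and computes skeleton-based reconstruction
    quality metrics (SWC I/O, resampling, Gaussian smoothing, per-section
    alignment displacement, skeleton-to-skeleton agreement and error rates,
    pairwise arbor distance, box clipping, active-bout construction time).
    Includes a synthetic-data module that generates tissue-like volumes,
    sectioned and tiled image sets, and branching skeletons with complete
    ground truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
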