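Package: nucmorph
Title: Nuclear Morphometry and Migration Quantification for Transient
    Nuclear Softening Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for microscopy-based readouts of
    chromatin state and nuclear mechanics: the chromatin condensation
    parameter (CCP, Sobel edge density within segmented nuclei), nuclear
    aspect ratio (NAR) tracked across applied substrate strain, 3D cell
    infiltration depth and percent-migrated scoring from two-channel
    confocal z-stacks, scratch-wound closure kinetics, per-cell
    immunofluorescence intensity and percent-positive scoring,
    nascent-matrix area per nucleus, and differential-expression table
    filtering with set-overlap and fold-change correlation summaries.
    Includes a seeded synthetic-data generator that produces images,
    z-stacks, time series and DE tables with ground-truth sidecars so every
    stage is verifiable without raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
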