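Package: rdnamorph
Title: Morphometrics of rDNA and Nucleolar Organization in Fission Yeast
    Imaging Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the spatial organization of the ribosomal DNA
    (rDNA) arrays in fission yeast from two- or three-channel 3D
    fluorescence stacks carrying a DNA-supercoiling marker (GapR-GFP) and
    a nucleolar marker (Nhp2-mCherry).  Provides per-slice white top-hat
    background subtraction, Gaussian smoothing, full-histogram 3D Otsu
    segmentation, per-cell rDNA/nucleolar morphometrics (volume ratio,
    mean-intensity ratio, mCherry volume ratio, rDNA extension),
    cell-length staging and IQR outlier filtering; strain-level hit
    calling for arrayed deletion screens against control-anchored
    thresholds; colony-density scoring of Torin1 resistance in synthetic
    genetic arrays; normalization of fluorescence recovery after
    photobleaching (FRAP) traces; and a synthetic-data module that
    generates every input class with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
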