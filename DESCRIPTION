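Package: areaPloidy
Title: Ploidy and Genome-Size Inference from DAPI Image Cytometry of
    Nuclear Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: DNA image cytometry for coenocytic green algae and other
    organisms whose nuclear DNA content is read from DAPI-stained nuclear
    areas. Provides a synthetic generator of nucleus-area populations drawn
    from doubling-series mixtures and a renderer of synthetic fluorescence
    fields with ground truth; detection and morphological classification of
    nuclei, chloroplasts and bacteria in calibrated grayscale images;
    histogram-peak attribution of G1/G2 phases; gamete-anchored assignment
    of nuclei to Cx size classes on a doubling series with overlap
    splitting; cytotype and endopolyploidy inference; and the group
    comparisons (one-way ANOVA, pooled t tests) used to contrast minimum
    genome sizes between species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
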