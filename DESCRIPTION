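Package: srbratio
Title: Ratiometric Sulforhodamine B Quantification of Cardiomyocyte Hypertrophy
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Image-analysis pipeline for quantifying hypertrophic growth of
    cultured cardiac myocytes from in-situ sulforhodamine B (SRB) protein
    staining. Segments Hoechst-stained nuclei by isodata (intermeans)
    thresholding, classifies nuclear particles into mononucleated myocytes,
    binucleated myocytes and fibroblasts by area and circularity using
    log-normal mixture modelling, and computes a gain-invariant ratiometric
    growth index from extra-nuclear and nuclear SRB fluorescence. Includes
    Hill concentration-response and one-site inhibition fitting, growth-onset
    detection, exponential density-decay fitting, hierarchical (cluster-mean)
    ANOVA with intraclass correlation for technical repeats nested in
    biological isolations, a synthetic plate and image simulator with known
    ground truth, and a plate-level batch pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
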