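Package: spectrad
Title: Phantom-Based Robustness Screening of Quantitative SPECT Radiomic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Digital-phantom pipeline for screening the robustness of IBSI-style
    textural analysis (radiomic) features in quantitative SPECT. Simulates a
    uniform cylindrical phantom and a seven-syringe 'Revolver' insert inside a
    NEMA-style body with an image-domain imaging model (Gaussian point-spread
    function plus Poisson counting noise, per-radionuclide profiles for 99mTc
    and 177Lu), computes a 67-feature LIFEx-style catalogue (SUV statistics,
    histogram, shape, GLCM, GLRLM, NGLDM, GLZLM) with fixed-bin-width SUV
    discretisation, and applies the two-stage feature reduction: volume
    dependency over a 29-sphere VOI series and test-retest coefficient of
    variation across repeat scans of the Revolver inserts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
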