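Package: synapcover
Title: Inhibitory Synaptic Coverage Quantitation from Confocal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies inhibitory (GAD+) synaptic coverage of neuronal
    perikarya from two-channel confocal immunofluorescence images:
    intensity normalization, soma boundary segmentation, punctum
    detection, the coverage statistic C' = N_s / A(d), neuron size
    measurement, and image quality control.  Also provides
    semi-automatic colour-deconvolution quantification of DAB
    immunohistochemistry, genotype-stratified cohort statistics
    (Spearman correlations and covariate-adjusted linear models), and
    synthetic image and cohort generators with exact planted ground
    truth for validating the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    mgcv,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
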