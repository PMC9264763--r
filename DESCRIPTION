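Package: rsibreast
Title: Three-Compartment Restriction Spectrum Imaging for Breast Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Voxel-wise fitting of a fixed-spectrum three-compartment restriction
    spectrum imaging (RSI) model to multi-shell breast diffusion-weighted MRI by
    non-negative least squares, together with the surrounding analysis pipeline:
    synthesis of multi-shell DWI phantoms with known compartment fractions and
    Rician noise, noise-floor estimation and subtraction, shell averaging and
    percentile normalization, derived combination maps (C1*C2 and its square
    root) and mono-exponential ADC maps, region-of-interest median extraction
    with a 500-voxel contralateral healthy control, and the paired group
    statistics (ranked two-way repeated-measures ANOVA, exact Wilcoxon
    signed-rank tests with Bonferroni correction).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    car,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
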