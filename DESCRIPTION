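Package: moqam
Title: Motion-Artifact Image Quality Metrics for Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes ten magnetic-resonance image quality metrics (five
    reference-based: SSIM, PSNR, FSIM, VIF and a perceptual feature
    distance; five reference-free: Tenengrad, average edge strength,
    normalized gradient squared, image entropy and gradient entropy) on
    volumetric brain images under a configurable pre-processing grid
    (brain-mask handling, intensity normalization, slice selection and
    slice-wise reduction), and quantifies agreement between metric values
    and observer quality scores via weighted score fusion, Krippendorff's
    alpha, Spearman rank correlation and a median-rank league table. A
    synthetic phantom, k-space motion-artifact and simulated-observer
    module makes the full evaluation study reproducible without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
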