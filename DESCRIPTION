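Package: csiseg
Title: Two-Stage Organ-at-Risk Auto-Segmentation for Whole-Body CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A CPU-scale two-stage auto-segmentation framework for organs at
    risk on whole-body CT, aimed at pediatric craniospinal irradiation
    planning. Organs are first localized on digitally reconstructed
    radiographs (DRRs) by fusing orthogonal 2D bounding boxes into 3D regions
    of interest, then segmented by small organ-specific U-Net variants (basic,
    attention-gated, and 2.5D) on cropped mini-CT scans. Includes NIfTI I/O
    and shared preprocessing (body masking, canvas centering, label
    exclusivity, nearest-neighbor resampling), the Dice similarity coefficient
    with smoothing, a statistical comparison suite (Kruskal-Wallis with
    Holm-Bonferroni adjustment, Dunn post hoc, Mann-Kendall age trends with
    FDR control, Mann-Whitney group comparisons), and a synthetic whole-body
    phantom generator with exact ground-truth masks and an age covariate so
    that every pipeline stage can be trained and tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    withr,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
Config/testthat/edition: 3
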