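Package: atscreen
Title: Unsupervised Target Screening and Quantification for LC/GC-HRMS
    Ion Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An unsupervised workflow for targeted analysis of
    high-resolution mass-spectrometry batches. Extracted ion
    chromatograms are built from centroided mzML files, described as
    symbolic (SAX) sequences, and screened with a local-maxima peak
    walker that tolerates plateaus, shoulder bumps, and zigzag noise
    and splits merged peaks at contact points. Retention-time drift is
    corrected at three levels (batch-global from internal standards,
    intensity-dependent from calibrations, per-sample from assigned
    internal standards). Detected analytes are confirmed by qualifier
    ion ratios, masked against solvent blanks, matrix-corrected, and
    quantified by auto-trimmed weighted linear calibration with Cook's
    distance outlier removal. A seeded synthetic-batch generator and
    workflow-comparison metrics (sensitivity, specificity, accuracy,
    MAPE, Bland-Altman limits) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mzR,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
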