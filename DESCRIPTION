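Package: smquant
Title: Quantitative Single-Molecule Microscopy and Biophysics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of single-molecule localization microscopy (SMLM)
    point patterns, coordinate-based colocalization, 3D single-particle
    tracking, fluorescence recovery after photobleaching (FRAP),
    tight-binding titration isotherms, and atomic force microscopy (AFM)
    grain morphometrics.  Provides a linearised Ripley's K statistic with
    guard-band edge handling, DBSCAN cluster maps with convex-hull cluster
    metrics, per-localization degree-of-colocalization (DoC) scores,
    time-averaged mean-squared-displacement analysis with anomalous
    diffusion fitting and mobility classification, double/full-scale FRAP
    normalization with single-exponential recovery fits, quadratic
    ("ligand depletion") dissociation-constant fitting, and sigma-multiplier
    grain masking with caliper bounding sizes for AFM height maps.
    Synthetic-data generators (Thomas cluster processes, scaled Brownian
    trajectories, exponential FRAP recovery, quadratic titrations and
    worm-like-chain DNA scenes) provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    jsonlite,
    withr,
    EBImage,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
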