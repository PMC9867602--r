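Package: mesofiber
Title: Multiscale Corticostriatal Analysis of Widefield Calcium Imaging
    and Fiber Photometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous mesoscale widefield cortical
    calcium imaging and striatal fiber photometry. Provides dF/F normalization
    (isosbestic fit and moving-average baselines), zero-phase Chebyshev
    filtering, anti-aliased resampling, pixel-wise full and partial correlation
    maps, cross-correlation lag maps, convolutional sequential non-negative
    matrix factorization (seq-NMF) for spatiotemporal motif discovery,
    motif-photometry cross-correlation, stimulus-evoked epoching with
    habituation and activated-area statistics, and a seeded synthetic-session
    generator with planted ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
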