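Package: corvistopo
Title: Dynamic Anterior Corneal Curvature Topography from Air-Puff
    Scheimpflug Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the dynamic curvature topography of the anterior
    corneal surface from high-speed Scheimpflug video of an air-puff
    deformation (Corvis ST-style acquisitions). Corneal boundaries are
    segmented with contrast-invariant phase symmetry and asymmetry maps
    from a log-Gabor quadrature filter bank, after morphological removal
    of eyelash and tear artifacts. The per-column signed radius of the
    anterior surface is estimated with a non-iterative area-error circle
    fit over a sliding window, normalized through a piecewise map onto a
    rainbow palette, and fused with the grayscale frame in CIECAM02
    appearance space to render a per-frame curvature topography. A
    synthetic frame and deformation-sequence generator with exact
    analytic ground truth supports end-to-end validation, together with
    agreement statistics (central corneal thickness, peak distance,
    Bland-Altman limits, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
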