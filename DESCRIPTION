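Package: padrill
Title: Multi-Scale Ultrasound and Photoacoustic Navigation for Pedicle
    Screw Drilling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiation-free navigation and in-situ sensing toolkit for
    pedicle screw drilling, exercised end to end on synthetic spine and
    tissue phantoms. Provides a deterministic phantom generator
    (parametric lumbar vertebrae, tissue label maps, drill trajectories,
    tracked ultrasound frames, photoacoustic signals and endoscopic
    scans, and a packaged cancellous-bone absorption spectrum), freehand
    3D ultrasound volume compounding and bone-surface detection
    (including a small two-loss heatmap detector), hierarchical
    PCA-initialised radius-selective iterative closest point
    registration of ultrasound bone surfaces to per-level vertebra
    models, photoacoustic signal characterization with generalized
    contrast-to-noise ratio (gCNR) scoring, and safe/warning/dangerous
    drilling-zone classification over photoacoustic endoscopy timelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
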