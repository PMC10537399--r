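Package: backres
Title: Minimal Sampling and Camera Resolution for 3D Back-Surface Topography
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Determines the minimal spatial sampling resolution and the minimal
    camera resolution required to capture the three-dimensional shape of the
    human back, as needed when selecting optical 3D scanners for scoliosis
    screening and trunk-asymmetry analysis. Provides readers and writers for
    ASCII point clouds (PLY, OBJ, XYZ), horizontal slicing with uniform lateral
    regularization, per-slice spatial Fourier analysis with Nyquist and
    oversampling translation, controlled shape-quality degradation (zero-phase
    Butterworth low-pass filtering, random downsampling, depth quantization,
    uniform and sinusoidal noise) with mean-absolute-error sweeps and slope
    break-point detection, trunk symmetry-line extraction and its sensitivity
    to low-pass filtering, closed-form camera pixel-count requirements, and a
    band-limited synthetic back-surface generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
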