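Package: nmralign
Title: Whole-Spectrum Registration of 2D/3D NMR Spectra by Cross-Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Objective chemical-shift referencing for processed 2D and 3D
    NMR spectra. Treats frequency-domain spectra as images and estimates the
    global ppm offset between a reference and a moving spectrum by filtered,
    normalized FFT cross-correlation with parabola-based sub-pixel peak
    refinement. Handles spectra with differing spectral sampling, grid sizes
    and origins via Fourier-interpolation resampling and center-preserving
    resizing, and aligns 3D spectra to 2D planes through maximum-value or
    sum projections. Reads and writes single-file NMRPipe spectra and a
    plain-text spectrum dialect, and ships a deterministic synthetic-spectrum
    generator with exact sub-pixel ground-truth offsets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
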