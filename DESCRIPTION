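Package: eiphase
Title: Single-Image Phase Retrieval for Edge-Illumination X-Ray
    Phase-Contrast Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and single-image phase retrieval for
    edge-illumination (EI) X-ray phase-contrast imaging. The image
    formation model mixes refraction contrast along the scan direction
    (through the illumination curve of the slit system) with near-field
    free-space propagation, described by the transport-of-intensity
    equation, along the direction parallel to the slits. Under a constant
    delta/beta assumption a non-diverging complex Fourier-domain filter
    recovers the object thickness or projected electron density from one
    normalized image. Includes analytic and tabulated illumination
    curves, synthetic phantoms with known ground truth, Poisson noise
    injection, the classical two-image EI retrieval with one-dimensional
    integration as a baseline, streak-artefact metrics, float TIFF and
    CSV input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
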