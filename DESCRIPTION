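Package: spexim
Title: Spectral K-Edge Subtraction and Energy-Dispersive XAS Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for spectral K-edge subtraction (KES) imaging and
    wide-field energy-dispersive X-ray absorption spectroscopy (EDXAS) performed
    with bent-Laue monochromators. Converts stacks of energy-dispersed detector
    images (dark, flat, absorption-edge reference, and sample projections) into
    quantitative projected-density maps of candidate materials: flat/dark
    normalization, per-column absorption-edge localization, one-point and
    two-point energy-position calibration via Bragg's law, Gaussian
    energy-resolution estimation, per-column least-squares decomposition against
    reference mass-attenuation spectra, beam-decay correction, automatic
    rotation-center finding, and filtered back projection CT reconstruction.
    Includes a forward simulator of the energy-dispersive beamline so every
    stage can be exercised and validated without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, tiff, stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
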