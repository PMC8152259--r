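Package: afmorph
Title: Morphometric Analysis of AFM Topographies of Surface-Bound Protein Aggregates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of atomic force microscopy (AFM) height maps of
    protein aggregates on flat and nanopatterned substrates. Provides reading and
    writing of Gwyddion Simple Field (GSF) and ASCII height grids, plane and
    median-line flattening, RMS roughness, the one-dimensional height-difference
    correlation function with ripple periodicity and amplitude extraction, 2D FFT
    power spectra with anisotropy-peak detection, Fourier notch subtraction of
    periodic ripple backgrounds, height-threshold grain segmentation with
    zero-basis volume, projected boundary length and spreading coefficient,
    per-condition summary statistics, and a synthetic-topography generator with
    exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, EBImage, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
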