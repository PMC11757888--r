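Package: krawlet
Title: Shift-Invariant Krawtchouk Wavelet Localization of Impulse
    Components in Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Time-frequency analysis of non-stationary one-dimensional
    biosignals (EEG, ECG) built on discrete orthonormal Krawtchouk
    functions.  Projections of a signal onto the family of circularly
    shifted, asymmetry-parameterized Krawtchouk bases yield an energy
    functional whose maximum localizes transient impulse components
    (eye blinks, muscle bursts, QRS complexes) in time while the winning
    scale identifies their frequency band, sidestepping the usual
    trade-off between temporal and spectral resolution.  The package
    provides numerically stable basis construction, FFT-based shift
    spectra, a dyadic multiscale decomposition with threshold-gated
    event detection and exact residual bookkeeping, a classical
    Krawtchouk mother-wavelet transform as a shift-variant baseline,
    a seeded generator of EEG-like test signals with ground truth, and
    readers/writers for EDF and delimited text recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'basis.R'
    'localize.R'
    'multiscale.R'
    'classical.R'
    'synthetic.R'
    'io.R'
    'show-methods.R'
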