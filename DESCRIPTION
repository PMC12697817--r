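Package: protodyn
Title: Signal Analysis and Electrochemical Model Fitting for Proteinoid-Quantum-Dot Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for slow electrochemical oscillations recorded
    from proteinoid-quantum-dot hybrid networks: time-series preprocessing
    (baseline subtraction, common-axis interpolation, IQR outlier flags),
    descriptive oscillation statistics and dominant-frequency estimation,
    Welch power spectral density with log-log power-law slope fitting,
    spectrogram energy, magnitude-squared coherence, Hilbert envelope and
    phase analysis, binned Shannon entropy, a variance-based quantum Fisher
    information proxy, ASCII pulse-train stimulus encoding and amplitude
    modulation, square-wave voltammetry decay fits, Randles-circuit
    impedance, capacitance memory models, percentile-threshold Boolean
    logic gates, and toroid morphometry. Includes a seeded synthetic-data
    generator emulating the statistical structure of such recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    signal
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
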