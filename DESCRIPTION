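Package: excitrace
Title: Excitable Dual-Feedback Gene Circuit Simulation and Community
    Trace Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulation and qualitative analysis of a
    two-variable activator-repressor (IacR-MarR) dual-feedback gene
    circuit driven by antithetic auxin/salicylate stimulation:
    nullclines, fixed points, regime classification (steady, excitable,
    oscillatory), turnover-ratio bifurcation scans, refractory-period
    protocols and entrainment simulations.  Includes a synthetic
    generator of multi-community fluorescence trace data and the
    matching analysis pipeline: reporter normalisation, linear
    detrending, Savitzky-Golay smoothing, run-length peak detection,
    inter-peak periods, phase drift, synchrony index, cumulative
    autocorrelation and FFT power spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
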