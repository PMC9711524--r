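# excitrace

Simulation and analysis tools for a synthetic excitable gene circuit
that couples chemical inputs to pulsatile gene expression across
communities of cells.

A transcriptional activator (IacR) drives its own production and that
of a transcriptional repressor (MarR); MarR feeds back on the
activator. Two phytohormones act on protein turnover — auxin (IAA)
destabilises the activator, salicylate (SA) the repressor — so that
alternating ("antithetic") pulses of the two chemicals entrain the
circuit's expression pulses to an external clock. The package is aimed
at people studying excitable gene regulation and chemically entrained
expression rhythms: it provides the deterministic circuit model, its
qualitative analysis, and the signal-processing pipeline used on
community-level fluorescence recordings.

## The model

IacR (`I`) and MarR (`M`) concentrations follow

    dI/dt = a1 + b1 I^2 / (K_A^2 + I^2 + (gamma M)^2) - d1 (1 + eps_I IAA(t)) I
    dM/dt = a2 + b2 I^2 / (K_B^2 + I^2)               - d2 (1 + eps_M SA(t))  M

The turnover ratio `d1/d2` is the key bifurcation parameter: varying
it moves the circuit between a steady state, an excitable regime (one
stable rest state, large transient excursions after super-threshold
perturbations, followed by a refractory period), and relaxation
oscillations.

Package components:

* **Circuit model** — `simulate_circuit()` (adaptive stiff solver,
  square-wave edges handled exactly), `circuit_nullclines()`,
  `classify_regime()`, `bifurcation_scan()`, `refractory_protocol()`,
  with `circuit_params()` / `default_circuit_params()` (a calibrated
  excitable reference set) and `stimulus_program()` /
  `antithetic_stimulus()`.
* **Synthetic data** — `generate_traces()` builds multi-community
  fluorescence trace sets with amplitude variability, phase jitter,
  skipped cycles, drift and noise (`closed_loop`, `open_loop`,
  `control` presets); `generate_from_model()` simulates each community
  from the circuit with heterogeneous kinetics.
* **Trace analysis** — `analyze_traces()` runs the standard pipeline:
  mCherry normalisation, linear detrend, Savitzky–Golay smoothing
  (window 15), 0–1 rescaling, run-length peak detection
  (`nups = ndowns = 6`), inter-peak periods, cross-community phase
  drift, synchrony index `1 - R`, cumulative autocorrelation and FFT
  power spectra.
* **CLI** — `excitrace_cli()` plus the `inst/cli/excitrace` script:
  `simulate`, `nullclines`, `classify`, `scan`, `refractory`,
  `generate`, `analyze` subcommands with JSON/CSV artifacts and run
  manifests.

## Worked example

Generate a tightly entrained 30-community recording (2-h stimulus,
24 h at 10-min sampling) and analyse it:

```r
library(excitrace)

cfg <- generator_config(n_communities = 30, duration = 24, period = 2,
                        seed = 7, preset = "closed_loop")
traces <- generate_traces(cfg)
report <- analyze_traces(traces, expected_period = 2)
report
#> <synchrony_report>
#>   expected period     : 2 h
#>   pooled median period: 2 h
#>   dominant period     : 2.014 h (PSD), 2 h (ACF)
#>   synchrony index     : median 0.967 (IQR 0.041)
#>   structured          : TRUE
```

The pooled median inter-peak interval recovers the 2-h stimulus
period; the power spectrum and autocorrelation agree on the dominant
period within one frequency/lag bin; and the median synchrony index of
0.967 says a typical community's peaks deviate from the
cross-community reference by about 3% of a period. `structured = TRUE`
records that the mean autocorrelation has a significant periodic
component (a `control`-preset recording fails this flag).

The mechanistic side, from the same session:

```r
classify_regime(default_circuit_params())
#> <regime_label> excitable (peaks=0, ipi_cv=NA, excursion=4.81x)

refractory_protocol(default_circuit_params(), gap_hours = 2)
#> <refractory_result>
#>   pulse start end window_end peak_time  amplitude
#> 1     1     1  13         15        15 8.16162103
#> 2     2    15  27         39        39 0.01266813
#>   second/first response ratio: 0.002
```

A 50% kick to the rested activator fires a 4.8× excursion and
returns to rest (excitability); after a 12-h auxin pulse the circuit
responds on hormone removal, but a second pulse arriving 2 h later
elicits 0.2% of the first response — the refractory period stored in
the slowly decaying repressor.

## Vignette

`vignettes/excitable-circuit-methods.Rmd` documents the model and its
assumptions, the calibration logic behind every default parameter, the
regime structure along the turnover ratio, the numerical conventions
of the analysis pipeline, what the synthetic generator does and does
not emulate, and known limitations.
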