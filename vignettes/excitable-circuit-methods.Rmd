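---
title: "The excitable IacR-MarR circuit: model, calibration and trace analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The excitable IacR-MarR circuit: model, calibration and trace analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitrace)
```

## The model

`excitrace` simulates a two-variable synthetic gene circuit in which a
transcriptional activator (IacR) drives its own production and that of
a transcriptional repressor (MarR), while MarR widens the activator's
Hill denominator:

$$\frac{dI}{dt} = a_1 + \frac{b_1 I^2}{K_A^2 + I^2 + (\gamma M)^2}
  - d_1\,(1 + \epsilon_I\,\mathrm{IAA}(t))\,I$$

$$\frac{dM}{dt} = a_2 + \frac{b_2 I^2}{K_B^2 + I^2}
  - d_2\,(1 + \epsilon_M\,\mathrm{SA}(t))\,M$$

with $I$ = IacR and $M$ = MarR concentrations.  The phytohormones act
purely on turnover: auxin (IAA) accelerates degradation of the
activator, salicylate (SA) of the repressor.  Antithetic square-wave
stimulation (exactly one hormone present at any time, half a period
each) therefore alternates between *resetting* the activator and
*derepressing* it, which is what entrains the circuit's pulses to the
stimulus clock.

The model is deterministic; no stochastic (Gillespie/Langevin) variant
is provided, and the potassium-channel/membrane-potential output stage
downstream of the circuit is outside the model's scope — the IacR
trajectory serves as the reporter proxy.

### Assumptions worth making explicit

* Hormone action is instantaneous and multiplicative on turnover;
  transport, uptake and binding kinetics are absorbed into
  $\epsilon_I, \epsilon_M$.
* Both Hill exponents are fixed at 2, as in the source model family.
* Concentrations are in arbitrary units; time is in hours throughout.

## Nullclines and fixed points

Setting the hormone terms to zero, the MarR nullcline is available in
closed form, $M^{**}(I) = (a_2 + b_2 I^2/(K_B^2 + I^2))/d_2$.  The
IacR nullcline is obtained by inverting the repression term:
$(\gamma M)^2 = b_1 I^2/(d_1 I - a_1) - K_A^2 - I^2$, defined only
where the right-hand side is nonnegative and $d_1 I > a_1$ (below
$a_1/d_1$, basal production alone beats turnover and no amount of MarR
can hold IacR still).  `circuit_nullclines()` validates every returned
point against the vector field (residuals below $10^{-8}$ in scaled
units) rather than trusting any transcription of the algebra, and
locates fixed points by bracketed root finding on the difference of
the two curves.

## The calibrated default parameter set

The reference set returned by `default_circuit_params()` is

```{r}
unlist(default_circuit_params())
```

It was calibrated by the procedure the package documents as its own:
fix the Hill scales and the production/turnover structure, then tune
the repression strength $\gamma$ and the turnover pair $(d_1, d_2)$
until (i) the unforced circuit is excitable, (ii) the turnover ratio
traverses steady, oscillatory and excitable regimes, and (iii)
antithetic forcing entrains pulses 1:1 from 3 h down to 30 min
periods.  The design constraints that drove each number:

* **Sharp activator Hill, $K_A = 0.3$ below the rest IacR
  ($\approx 0.27$), $b_1/d_1 = 20$:** makes the post-pulse
  "ignition corridor" fast, so that the excursion fired when a long
  auxin pulse is removed peaks within ~1–2 h.
* **Repressor Hill half-max above rest, $K_B = 3$:** at rest only
  ~1% of the repressor drive is engaged, so basal MarR
  ($a_2/d_2 \approx 0.19$) sits far below rest MarR ($\approx 0.9$).
  After a long auxin pulse MarR has decayed to basal, the corridor is
  wide open, and the removal response fires immediately; during an
  excursion IacR reaches $\sim 10$, the Hill term saturates, and MarR
  overshoots strongly — that overshoot is the refractory memory.
* **$\gamma = 9.54$, 0.3% above the oscillation boundary:** the rest
  state sits just on the stable side of the boundary, so a 50% kick
  to IacR crosses the nearby threshold and triggers a full
  ($\approx 5\times$) excursion that returns to rest — the operational
  definition of excitability used by `classify_regime()`.
* **$d_2 = 0.08\,h^{-1}$:** slow repressor turnover stores the
  refractory memory across a 12-h auxin pulse
  ($e^{-12 d_2} \approx 0.38$ of the overshoot survives).
* **$d_1 = 3\,h^{-1}$:** fast activator turnover lets the removal
  response develop inside a 2-h inter-pulse gap.
* **$\epsilon_I = 5$, $\epsilon_M = 80$:** asymmetric on purpose.
  Salicylate must crush MarR within a quarter of the fastest (30-min)
  stimulus period to trigger one pulse per cycle, hence the large
  $\epsilon_M$.  Auxin only needs to reset IacR; a moderate
  $\epsilon_I$ leaves the reset shallow so the next cycle's rise
  starts immediately, which keeps the rising run long enough for the
  peak detector at coarse sampling.  (Equal sensitivities cannot
  satisfy both requirements at 30-min forcing.)

### Where the regimes live

`bifurcation_scan()` varies the turnover ratio $d_1/d_2$, the
circuit's key bifurcation parameter.  On the calibrated set (varying
$d_2$, with $d_1$ fixed at 3), the bands are:

* ratio $\lesssim 2.5$: **steady** (fast repressor turnover keeps MarR
  too low to oscillate; the circuit rests at a high-activator state);
* ratio $\approx 2.5$–$37$: **oscillatory** (relaxation oscillations,
  period growing with the ratio);
* ratio $\approx 37$–$40$: **excitable** (the calibrated default at
  37.5 sits here, just past the oscillation boundary);
* beyond $\approx 40$: **steady** again (deep repression: the rest
  state is far from threshold).

Two remarks.  First, the traversal order along the ratio axis is
steady → oscillatory → excitable, with excitability in a narrow band
hugging the oscillation boundary — which is where excitable dynamics
generically live in two-variable activator–repressor systems.  Second,
the excitable band necessarily sits at large ratios for any parameter
set that also reproduces the refractory protocol: memory across a
12-h auxin pulse requires $d_2 \lesssim 0.1\,h^{-1}$, a removal
response inside a 2-h gap requires $d_1 \gtrsim 2\,h^{-1}$, and
together these force $d_1/d_2 \gtrsim 20$.  A scan restricted to the
ratio window $[0.1, 10]$ therefore shows only the steady and
oscillatory bands; we verified empirically (wide randomized searches
over all shape parameters) that at $d_2 \gtrsim 0.2$ the
steady/oscillatory boundary is a supercritical Hopf bifurcation with
no excitable window at all, so this trade-off is a property of the
model class, not of one unlucky parameter choice.

### Classification conventions

`classify_regime()` labels *oscillatory* when the unforced system
shows at least 3 peaks with inter-peak CV < 0.1 in the second half of
its window, *excitable* when the rested system is quiet but a 50%
IacR kick triggers an excursion exceeding 3× the rest level before
returning to rest, and *steady* otherwise.  The classification window
defaults to `max(48, 40/min(d1, d2))` hours: near the excitable
boundary the limit-cycle period grows like several multiples of
$1/d_2$, and a fixed 48-h window would miss slow oscillations
entirely.  The thresholds (kick 0.5, excursion 3×, CV 0.1) are
insensitive to ±50% changes on the calibrated set.

### The refractory protocol

`refractory_protocol()` applies two 12-h auxin-only pulses.  During a
pulse, IacR is degraded and MarR relaxes to its basal level; on
removal, IacR rebounds through the open corridor and fires a full
excursion, which pumps MarR far above rest.  A second pulse arriving
2 h later finds MarR still high after its own 12 h of decay, so the
second removal response is blocked (the measured ratio on the default
set is ~0.002).  The response attributed to each pulse is the maximum
IacR elevation above rest between that pulse's end and the next
pulse's start (or the end of the record).  Recovery is governed by the
slow repressor decay: with a gap of `5/min(d1, d2)` hours (much longer
than the recovery time) the two responses agree to 0.1%.

## Entrainment and the analysis pipeline

The trace pipeline reproduces the standard workflow for community
fluorescence recordings: optional reporter normalisation
`green/(green+red)` against a constitutive marker, per-community
linear detrending, Savitzky–Golay smoothing (window 15 samples, order
4), 0–1 rescaling, run-length peak detection (`nups = ndowns = 6`,
minimum height 0.2 on the rescaled signal), then inter-peak periods,
cross-community phase drift, the synchrony index $1 - R$, the
cumulative (community-averaged) autocorrelation and the mean FFT
periodogram.

Numerical conventions, chosen once and exposed as configuration:

* **Savitzky–Golay edges** are filled by evaluating the polynomial
  fitted to the first/last full window (no zero padding).  Interior
  points equal the classic convolution weights; tests verify both
  against an explicit normal-equations fit and against the standard
  implementation used in this field's analysis scripts.
* **Peak runs are strict**: a step of exactly zero breaks a rising or
  falling run.  A bump with only five rises on a flat baseline is not
  a peak at `nups = 6`.  Plateau summits are reported at their maximum
  sample.
* **Peak width** is full width at half prominence, with prominence
  measured above the higher of the two minima separating a peak from
  its detected neighbours; widths are interpolated linearly.
* **Peak amplitudes** are reported on the smoothed, pre-rescale signal
  (rescaling destroys amplitude information).
* **Phase drift** matches peaks to stimulus cycles by
  nearest-peak-within-half-a-period against a per-cycle reference; the
  reference is the cross-community median peak time (default) or a
  fixed stimulus clock (`reference = "clock"`).  The synchrony index
  of a community is $\max(0, 1 - \langle|\mathrm{drift}|\rangle/T)$.
* **Autocorrelation** uses the biased estimator (lag sums divided by
  $n$, normalised to 1 at lag zero) — stable for short records; note
  the $(1 - \ell/n)$ shrinkage of distant lags.
* **The periodogram** is one-sided and normalised so that it sums to
  the biased variance (Parseval); the dominant period is the
  reciprocal of the peak frequency.
* A report is flagged *structured* when the mean autocorrelation has a
  local maximum beyond its first zero crossing exceeding
  $3/\sqrt{n}$; unstimulated/control recordings fail this test.

### Sampling and the run-length detector

With `nups = ndowns = 6`, two peaks can never be detected closer than
12 samples apart.  At the 10-minute imaging cadence this caps
detectable rhythms at periods ≥ 2 h; the 1-h and 30-min entrainment
analyses therefore sample at $T/15$ (4-minute and 2-minute grids), the
same samples-per-cycle ratio as the 10-minute cadence gives a 2.5-h
rhythm.  Even at 12 samples per cycle, detection of every single cycle
requires the processed waveform to rise for exactly half the cycle and
fall for the other half; sub-sample timing jitter flips marginal
cycles, which is why the synthetic generator models community phase as
persistent (see below).

## The synthetic data generator

`generate_traces()` emulates extracted per-community fluorescence
traces: one pulse per stimulus cycle (difference-of-exponentials
kernel, rise $0.1\,T$, decay $0.25\,T$), lognormal per-community and
per-peak amplitude factors, Bernoulli cycle skipping, a linear
baseline drift, additive Gaussian noise, and phase jitter decomposed
into a persistent per-community phase offset (90% of the jitter SD)
plus per-cycle timing noise (44%), totalling the configured per-peak
SD.  The decomposition reflects how entrained communities actually
behave — each community holds a stable phase relative to the common
stimulus while individual pulses wander — and it keeps each trace
locally periodic, which matters for the marginal 12-samples-per-cycle
detection geometry described above.

Three presets bracket the qualitative open- vs closed-loop contrast:
`closed_loop` (jitter SD $0.05\,T$, 2% skips), `open_loop` (jitter SD
$0.25\,T$, 30% skips, doubled amplitude spread) and `control` (no
pulses: baseline, drift and noise only).  The preset magnitudes are
package conventions, not measurements: no noise model for the real
recordings is published.  What the generator deliberately does *not*
emulate: cell growth and crowding dynamics, image segmentation
artefacts, photobleaching (beyond linear drift), non-Gaussian shot
noise, and any cell-to-cell coupling within a community.  Passing
round-trip tests therefore demonstrates that the pipeline recovers
known structure of this idealised form, not that it is robust to every
pathology of real microscopy data.

`generate_from_model()` instead simulates each community from the
circuit itself with lognormally jittered kinetic parameters — the
bridge between the mechanistic and phenomenological halves of the
package: heterogeneity in kinetic rates degrades the synchrony index
monotonically.

## Problem sizes and determinism

The test suite and the acceptance script run deterministic
simulations (adaptive LSODA, relative tolerance $10^{-8}$, absolute
$10^{-10}$, integration restarted at every square-wave edge so edges
are not smeared) of 6–30 h at 2–10-minute sampling, synthetic cohorts
of 10–30 communities over 24 h, and Monte-Carlo comparisons over 50
paired seeds; everything completes in about a minute on one core.
Solver output is cross-checked against a fixed-step fourth-order
Runge–Kutta oracle at step $10^{-3}$ h, and every statistical stage
against direct-sum or brute-force oracles, in the regular test suite.

## Known limitations

* The excitable band of the calibrated set is narrow in $\gamma$ and
  in $d_1/d_2$; the package treats the calibrated numbers as a
  versioned reference, not as a robust region of parameter space.
* The refractory/entrainment timescale analysis above implies the
  model cannot place excitability at turnover ratios near 1 while
  reproducing the 12-h-pulse refractory experiment; if the real
  circuit does both, it contains slow variables beyond this
  two-variable reduction.
* The synchrony index depends on the choice of per-cycle reference;
  both supported conventions (cross-community median, fixed stimulus
  clock) are reported relative to an *expected* period that must be
  supplied.
* Peak detection near the 12-samples-per-cycle limit is inherently
  marginal; analyses of fast rhythms should sample at $\ge 15$
  samples per cycle.
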