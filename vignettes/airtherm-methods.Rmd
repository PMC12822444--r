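---
title: "Modelling the thermoelectric response to physiological airflow"
author: "airtherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the thermoelectric response to physiological airflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airtherm)
```

## The physical model

A wearable thermoelectric device (TED) sits between the skin (held at
`Tlower`) and the air.  Airflow at speed $v$ and temperature $T_{air}$
sweeps the upper face and exchanges heat convectively,

$$ q_{conv} = h A\,(T_{air} - T_{upper}), $$

with the convective coefficient given by the average laminar flat-plate
correlation

$$ h = \frac{\kappa}{L}\,\mathrm{Nu}
     = 0.664\,\frac{\kappa}{L}\,\mathrm{Re}^{1/2}\,\mathrm{Pr}^{1/3},
  \qquad \mathrm{Re} = \frac{\rho v L}{\mu}. $$

The upper face is treated as a lumped thermal mass ($m$, $c_p$), so

$$ \frac{dT_{upper}}{dt} = f(v)\,(T_{air} - T_{upper}), \qquad
   f(v) = \frac{h(v)\,A}{m c_p}, $$

and the Seebeck readout is $V = \alpha\,(T_{upper} - T_{lower})$.  For
constant inputs the ODE has the closed form
$T_{upper}(t) = T_{air} - (T_{air} - T_{upper}(0))\,e^{-f t}$, implemented
in `stepResponse()`.  Breathing therefore appears as an alternating
voltage: warm exhaled air ($\approx 38^\circ$C) drives $V$ up, cool
ambient inhalation drives it down.

Key modelling commitments:

* **Forced convection only.** $h(0) = 0$; there is no natural-convection
  floor.  A quiet device simply holds its temperature.
* **Scalar speed.** The flow is taken normal to the plate; $v \ge 0$ is a
  scalar.
* **Constant skin temperature.** `Tlower` is fixed; skin-coupled dynamics
  are out of scope.
* **Kelvin internally.** Celsius is accepted only at file/config
  boundaries (`celsiusToKelvin()`, the `t_air_C` CSV column, the `TlowerC`
  config key).

## The time-varying integrator

The closed form exists only for constant inputs.  `simulateResponse()`
treats $v(t)$ and $T_{air}(t)$ as piecewise constant over each sampling
interval and applies the exact exponential update per interval.  This
makes the scheme unconditionally stable, exactly energy-consistent per
step, and *identical* to the closed form on constant inputs (the suite
checks agreement to $10^{-9}$ K), which a generic Runge--Kutta step would
not be.

## The one-dimensional leg solver

For velocity-sweep studies the lumped picture is replaced by steady-state
conduction along a thermoelectric leg with Joule source,
$\frac{d}{dx}(\kappa_{TED} \frac{dT}{dx}) + \rho_{TED} j^2 = 0$, current
continuity ($j$ uniform in 1-D), and the generalized Ohm's law
$j = -\sigma(\frac{dE}{dx} + \alpha \frac{dT}{dx})$.  The Seebeck
coefficient is constant, so the Thomson term vanishes identically — a
modelling choice, stated rather than silently dropped.  Boundary
conditions: Dirichlet `Tlower` at the skin face, Robin
$\kappa_{TED} T' = h(T_{air} - T)$ at the air face, side faces adiabatic,
no radiation.  Discretization is second-order central differences with a
ghost node at the Robin face and a direct solve (101 nodes by default; the
discrete solution is exact for the linear/quadratic profiles that constant
properties produce, which the grid-halving test confirms).  `solveLoaded()`
couples the conduction solve to an external resistance by fixed-point
iteration on the current (tolerance $10^{-8}$ relative, typically 3--5
iterations); delivered power peaks at the matched load, as it must.
`coupleSweep()` runs a p/n pair (published constants: $\alpha_p = 202.5$,
$\alpha_n = -210\ \mu$V/K; $\sigma_p = 9.25$, $\sigma_n = 10 \times 10^5$
S/m; $\kappa_p = 0.927$, $\kappa_n = 0.965$ W/(m K); legs
$1.4 \times 1.4 \times 2.5$ mm) over inlet velocities and reports
$|\Delta T|$ and $|V_{oc}|$, both strictly increasing in $v$ when the air
is colder than the skin — the qualitative trend the full 3-D simulation
shows.  Only the trend is claimed: the published magnitudes are
figure-only, and the device's absolute outputs (e.g. 139.7 mV at
$\Delta T = 30$ K) depend on a couple count that is not public, so the
per-couple identity $V = (\alpha_p - \alpha_n)\Delta T$ (412.5 $\mu$V/K
per couple) is what the package asserts.

## What the synthetic generators emulate

No recorded human data ship with the package; every experiment runs on
seeded synthetic signals whose defaults encode the study conditions:

* **Breathing** (`genBreathFlow()`): half-sinusoid exhale lobes at
  38 °C alternating with inhale lobes at ambient; normal tidal breathing
  at 15 breaths/min with peak exhale velocity 1.8 m/s, inside the
  measured 0.5--2.5 m/s range (and clipped to 2.5 after noise); `feeble`
  at 0.35 m/s emulating a flow restrictor; `weightless` cycles that are
  quiescent apart from a 0.5 s near-zero-flow gap followed by an exhale
  transient (a short free-fall surrogate).
* **Speech** (`genSpeechFlow()`): phrases are burst templates — one
  airflow burst per syllable group, with jittered onsets and peaks.  The
  five canonical classes ("HELP", "YES", "NO", "no pains no gains",
  "How are you") differ in burst count, timing and amplitude.  Distress
  shouts ("Help me", "Ah", "Oy") are voiced at raised airflow
  ($\ge 2.6$ m/s) versus conversational phrases ($\le 1.6$ m/s), because
  shouting is louder airflow; "Oy" is a repeated shout.  In multi-second
  recordings the phrase repeats every $\sim$2.7 s, as people calling out
  do.
* **Coughs** (`genCoughTrain()`): sharp gamma-shaped transients with peak
  velocities 1.2 / 3 / 8 m/s for mild / moderate / severe.  The spread is
  deliberately wide because the convective response compresses contrasts
  twice (as $\sqrt{v}$ and again through exponential saturation).
* **Heartbeat** (`genHeartbeat()`): two-Gaussian PPG pulses (systolic +
  dicrotic) at jittered beat times; resting 60 bpm / CV 3 %, exercising
  120 bpm / CV 5 %, abnormal (pain-stimulus surrogate) 75 bpm / CV 15 %
  with the pulse amplitude halved over the middle third.
* **Fusion datasets** (`genFusionDataset()`): balanced over the four
  (airflow state, heartbeat state) combinations; abnormal airflow draws
  from distress speech, feeble or weightless respiration; every airflow
  trace passes through `simulateResponse()` so the Seebeck identity holds
  pointwise; the fused label is the conjunction rule — abnormal iff
  A-TEDS *and* A-HBS.

All generators are pure functions of (parameters, seed); child seeds are
derived from one root.  Sampling is 100 Hz, which covers breathing, burst
envelopes and PPG morphology at desk scale.  Noise is additive Gaussian
velocity noise (0.02 m/s) plus a slow sinusoidal drift.

What the generators do **not** emulate: acoustic speech, true
cardiorespiratory coupling, subject-to-subject variability, sensor
electronics noise, or motion artefacts.  Classifier accuracies on these
data therefore demonstrate that the pipeline is correct and that the
encoded class structure survives the thermoelectric forward model — they
are not evidence about recognition of real human recordings.

## Cough detection and the alarm rule

A cough's voltage rise scales with the air--surface temperature contrast
available when it strikes, so raw rise amplitude conflates flow speed
with thermal history.  `detectCoughs()` therefore bands each detected
peak on the *normalized* rise
$\Delta V / (\alpha\,(T_{exh} - T_{pre}))$ — the fraction of the
available contrast the event converts — where $T_{pre}$ is read off the
trace at the preceding minimum and $T_{exh}$ is the 38 °C exhale
assumption.  Prominence over the preceding 0.6 s minimum (rather than a
global baseline) keeps one cough's decay tail from biasing the next
event's amplitude.  The band edges (0.10 detect / 0.245 moderate / 0.335
severe) were calibrated once against the generator's three intensities
run through the default device and live in `coughThresholds()` as
configuration; with them, the three intensity distributions are disjoint
across seeds and starting temperatures.  The alarm rule is exact logic:
at least 3 *severe* events inside any 5 s window (window anchored at each
severe event; closed interval; non-severe events never count).

## Classifiers

* **Speech** (`trainSpeechClassifier()`): short-time Fourier features
  (Hann window, 0.5 s frames, 0.25 s hop, log magnitude average-pooled to
  a fixed 12 × 8 grid) feed a fully-connected softmax network (`nnet`,
  one hidden layer of 32 units, weight decay $10^{-3}$), trained under
  the 9 train / 1 test per-class protocol with 10 samples per class.
  A single hidden layer is enough here because the pooled spectra are
  nearly linearly separable; the acceptance surface is accuracy, not
  architecture.
* **Fusion** (`trainFusionClassifier()`): per-channel spectral vectors are
  concatenated with channel-appropriate framing — 1 s frames capped at
  15 Hz for the thermally low-passed voltage trace, 2 s frames capped at
  12 Hz for the PPG trace so that 0.25--1 Hz beat-rate and rhythm
  differences are resolvable — and a gradient-boosted tree ensemble
  (xgboost, depth 5, 400 rounds, learning rate 0.1, single thread) learns
  the fused label with a stratified 25 % hold-out.  Depth 5 (rather than
  minimal stumps) lets individual trees express the cross-channel
  conjunction; the surrogate dataset uses 96 recordings per combination
  (384 per seed, 8 s each), the scale at which the conjunction is
  reliably learnable.  Accuracies are reported as mean over seeds; no
  hypothesis testing is claimed.  The shuffled-label null control sits at
  its chance band — between the prior-squared rate (0.625) and the
  majority rate (0.75) for the 1:3 class prior, not at 0.5.

## Numerical and design notes

* Degenerate inputs are rejected early: non-monotone time grids, negative
  velocities, empty templates, single-class training sets, classes with
  fewer than 10 samples under the 9/1 protocol.
* `v = 0` gives $f = 0$ and an exact hold; the $f \to 0$ limit of the
  per-step energy integral is taken analytically.
* Voltage traces carry their $\alpha$ and `Tlower` so the identities
  $\Delta T = T_{upper} - T_{lower}$ and $V = \alpha \Delta T$ are
  class invariants, enforced at construction.
* Determinism: every stochastic routine scopes its RNG
  (`withr`-style save/restore) and derives child seeds from one root;
  xgboost runs single-threaded.
* Spectrogram frames follow the `signal::specgram` convention (first
  frame starts at the first sample); the suite checks the first frame
  against a direct FFT and Parseval's identity.
* Problem sizes in the shipped tests and the acceptance script — 10
  samples per speech class, 96 recordings per fusion combination, 20
  seeds — are the package's desk-scale defaults, chosen so a full run
  completes in minutes on a laptop while the accuracy estimates are
  stable to well under one percentage point.

## Known limitations

* The lumped plate reaches $T_{air}$ at any $v > 0$ as $t \to \infty$;
  steady-state velocity dependence requires the conduction-limited leg
  model (`coupleSweep()`), not the lumped one.
* Absolute device voltages are not comparable to published hardware
  numbers (unknown couple count, placeholder plate geometry); per-couple
  and trend statements are.
* The cough thresholds are calibrated to the default device scale; a
  different `alphaDevice` or plate requires recalibration (they are
  configuration for exactly this reason).
* Real cough/speech airflow is turbulent and three-dimensional; the
  flat-plate laminar correlation is used throughout, consistent with the
  theory being modelled, not with cough fluid mechanics.
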