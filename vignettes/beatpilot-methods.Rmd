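---
title: "Beat pilot tone motion sensing: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat pilot tone motion sensing: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatpilot)
```

## The sensing mechanism

A pilot tone (PT) is a continuous RF tone transmitted into the scanner room
and picked up by the imaging receive coils; motion of the body or the coils
modulates its received amplitude and phase, so the per-readout tone
amplitude is a free motion navigator. A *beat* pilot tone (BPT) transmits
two tones at microwave frequencies $f_1 < f_2$ chosen so that the
second-order intermodulation product at $f_2 - f_1$ lands inside the MR
receiver band. The receive preamplifier is weakly nonlinear; writing its
memoryless transfer as $y = a_1 x + a_2 x^2$, the cross term of the squared
two-tone input creates a new spectral line at the difference frequency.
Because each tone's field above the bore's waveguide cutoff forms a standing
wave, and the received beat is the *product* of the two coil fluxes,
coil motion across the standing-wave pattern modulates the beat far more
strongly than it modulates a single below-cutoff tone.

Three analytic submodels carry this chain end to end:

1. **Bore electromagnetics.** The bore is an air-filled circular waveguide
   of radius $a$ with perfectly conducting walls. A mode (TE or TM, indices
   $n, m$) cuts off at $f_c = p\,c/(2\pi a)$ where $p$ is the $m$-th
   positive root of $J'_n$ (TE) or $J_n$ (TM). Below cutoff the axial
   wavenumber is imaginary and the field decays at
   $\alpha = (2\pi/c)\sqrt{f_c^2 - f^2}$ Np/m; above cutoff it propagates
   with guide wavelength $\lambda_g = c / (f \sqrt{1 - (f_c/f)^2})$. For
   the default 0.35 m radius the dominant TE11 mode cuts off at
   `r round(mode_cutoff("TE", 1, 1, 0.35) / 1e6, 1)` MHz, which is why a
   127.8 MHz tone decays along the bore while 2.4 GHz tones resonate.
2. **Nonlinear reception.** With the output-referred second-order intercept
   point IP2, the beat power obeys
   $P_\mathrm{IMD} = (p_1 + g) + (p_2 + g) - \mathrm{IP2}$ (dBm), a slope-2
   law; the equivalent polynomial coefficients are
   $a_1 = 10^{g/20}$, $a_2 = a_1^2 / A_\mathrm{IP2}$, under which the dB law
   and the time-domain spectrum agree exactly (this identity is tested to
   0.1 dB over a 30 dB sweep). The received beat series is modelled as
   $\overline{\Phi_1}\,\Phi_2$ per sample, so its magnitude is
   $|\Phi_1||\Phi_2|$ and its phase the tone phase difference.
3. **k-space embedding.** Tones ride inside each readout line at a fixed
   frequency offset, phase-continuous across lines (the transmitters share
   the scanner clock). Extraction is an exact single-frequency correlation
   per line and coil, which avoids the scalloping loss of nearest-bin FFT
   peak picking for off-grid tones (the FFT-bin mode is kept as an option).

## Deliberate simplifications of the field model

The reference treatment of this problem uses a full-wave finite-element
solve; this package substitutes a truncated modal expansion because it is
analytic, fast and testable, and it reproduces the mechanism under study
(standing waves above cutoff, evanescent decay below, flux products with
frequency-dependent modulation). Three simplifications are intentional:

- **Scalar axial cavity response.** Each mode's axial dependence — direct
  wave plus all end reflections, summed as a geometric series — multiplies
  the full transverse mode pattern. The sign flip of transverse components
  in backward-travelling waves is not tracked. Consequences covered by
  tests: travelling-wave magnitude is exactly flat with matched ends,
  standing-wave maxima are exactly $\lambda_g/2$ apart with reflective
  ends, and evanescent decay has exactly slope $-\alpha$.
- **Point-dipole source coupling.** Each mode (both degenerate azimuthal
  orientations for $n \ge 1$) is excited in proportion to its magnetic
  field at the source location projected on the source orientation,
  normalised to unit total excitation. Real antennas have patterns; none is
  modelled.
- **Empty bore.** No body, cradle or cable structures. The mode set
  defaults to all modes with cutoff below 1.5x the operating frequency,
  always including the 8 lowest-cutoff modes so below-cutoff operation
  retains an evanescent field, capped at 50 modes.

Because of these choices the *quantitative* modulation percentages of the
modal model are its own, not reference values; only the qualitative
frequency ordering (more peaks, larger modulation, greater coil-to-coil
diversity at higher transmit frequency) is asserted, and it is. The
supplementary closed form for the maximum possible peak count of a sweep is
not available in the source text, so peak counting is empirical
(`count_peaks` prominence rule) and only monotonicity across frequency is
claimed.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| bore radius / length | 0.35 / 1.35 | m | wide-bore 3 T geometry |
| end reflection | 1 | — | reflective end planes guarantee standing waves |
| coil size | 0.10 x 0.14 | m | posterior array element |
| flux quadrature | 8x8 doubled to <1e-6 rel., cap 128 | — | Gauss–Legendre tensor rule |
| tone pair | 2400 / 2527.8 | MHz | beat at 127.8 MHz |
| receiver BW / TR | 250 kHz / 4.4 ms | | readout geometry of the emulated sequence |
| low-pass cutoffs | 2 (respiration), 5 (vibration), 14 (bulk), 15 (dBCG regression), 25 (cardiac) | Hz | per-experiment smoothing, all zero group delay |
| accel high-pass | 2.5 (vibration) / 4 (cardiac) | Hz | drift rejection before double integration |
| Savitzky–Golay | window 11, order 4 | samples | frame-series denoising |
| low-mean exclusion | 0.1 x median \|mean\| | — | percent modulation of near-zero channels is meaningless |
| speed of light | 299 792 458 | m/s | CODATA |

Filter family and order are not dictated by the method description; a
5th-order Butterworth applied forward–backward is the package default, with
the order exposed. Each pass is anchored at the signal's initial value and
padded by reflection scaled to the slowest pole's time constant, so DC gain
is exact and edge transients are suppressed.

## Signal-processing conventions

- **Percent modulation** $(x/\bar{x} - 1)\times 100$ is scale-invariant and
  zero-mean; channels whose $|\bar{x}|$ falls below 0.1x the median channel
  mean are excluded rather than divided.
- **Relative phase** is the unwrapped argument of the windowed complex
  least-squares scale mapping a reference coil onto each coil. The full
  record is the default window (one scale per coil); sliding windows give
  time-resolved phase. This windowed-pseudo-inverse reading of the phase
  pipeline is an interpretation — the original description is terse — and
  is flagged as such here; the common-mode phase cancels by construction
  either way.
- **Displacement from acceleration** zero-phase high-passes, then
  trapezoid-integrates twice, de-meaning after each pass to bound drift —
  standard ballistocardiography practice.
- **Repeat alignment** uses integer-lag cross-correlation only; no
  sub-sample interpolation is attempted because averaged repeats with SD
  bars do not require it.
- **Gradient-artifact correction** is OLS projection on supplied surrogate
  regressors plus intercept, per coil; the artifact physics (Lorentz-force
  vibration of structures in the static field) is represented only
  phenomenologically as an additive regressor.
- **IMD convention**: IP2 is output-referred, matching a measurement in
  which fundamental and product are both read at the device output. Only
  second-order products get a power law; the polynomial tool accepts a
  cubic term for completeness.
- **Beat phase**: the conjugate-product convention makes the second-order
  trigonometric identity exact, but phase-level claims are model-defined;
  magnitude-based processing is the validated path (real receivers add
  AM–PM and other phase effects that are not modelled).

## The synthetic scenarios

All generators are deterministic given `seed` and emit a config hash into
their outputs.

- **Translation sweep**: 3 posterior coils, 10 cm travel, 5 triangular
  periods; pilot flux and beat flux-product envelopes embedded as two
  bin-aligned tones (so the extraction kernels are orthogonal). The sweep
  grid is 41 offsets by default; tests and examples use 15–21 offsets with
  a 16-point quadrature cap, which resolves the ~6 cm standing-wave period
  with margin.
- **Vibration**: 1 cm cradle steps at 100 mm/s exciting a damped 12 Hz
  oscillation (damping ratio 0.04; the return step 2.5x more damped), 5 s
  rests; a synthetic accelerometer records the same displacement. The
  oscillation frequency and damping are package choices of plausible
  mechanical values; the log-decrement of the extracted envelope recovers
  the configured damping within 5%.
- **Physiology**: respiration regimes (chest/stomach/rapid), optional bulk
  steps, and a cardiac component blending a smooth blood-volume wave (one
  peak per beat) into a sharp three-Gaussian dBCG-like wave train as the
  transmit frequency crosses ~1.2 GHz (logistic blend, width 0.2 GHz — a
  smooth stand-in for the observed mechanism change, not a hard switch).
  A `stiffness` factor scales the dBCG term: rigid coils amplify body
  vibration, flexible ones damp it; `stiffness = 0` reverts to the
  blood-volume shape. The three-Gaussian template (latencies 0.16/0.24/0.32
  s, amplitudes −0.45/1.0/−0.55) is a package parameterisation of the
  I/J/K-wave morphology and is exposed in code.
- **MIMO head motion**: 115 calibration frames rastering a ±3 mm / ±4°
  six-parameter rigid box (incommensurate triangle waves per axis), then 50
  inference frames of two one-dimensional motions — yaw "shake" and pitch
  "nod" — through the shared rest pose. Channel envelopes are seeded
  quadratic response surfaces of the rigid parameters (22 coils x 2
  antennas, stacked 115 x 44); no physical model of a rigid head coil's
  response exists in the source material, so smooth random surfaces stand
  in, with pilot-tone channels noisier than beat channels. The
  calibration-PCA → projection → regression pipeline recovers the
  registration principal components with $r \ge 0.95$ and the two inference
  motions form crossing one-dimensional score trajectories.

### What the generators do not emulate

No anatomy or tissue electromagnetics (body loading, conductivity changes),
no image encoding or reconstruction, no receiver gain compression or AM–PM,
no vendor raw formats, no gradient-waveform-accurate artifact synthesis
(a surrogate regressor channel suffices for the correction step). Passing
tests therefore demonstrate the internal consistency of the models and the
correctness of the analysis chain on signals with known ground truth — not
agreement with in-vivo acquisitions, whose headline statistics (e.g.
multicoil regressions against measured dBCG) depend on real hardware and
subjects.

## Numerical choices and degenerate inputs

- Bessel roots by sign-change bracketing plus `uniroot` to 1e-13; the test
  suite checks the first ten TE and TM modes against an independent plain
  bisection to 1e-9 relative.
- Flux quadrature doubles an 8x8 Gauss–Legendre grid until successive
  estimates agree to 1e-6 relative (cap 128); scenario sweeps accept looser
  settings, stated above.
- Exact cavity resonances (denominator of the reflection series ~ 0) are
  guarded by a small added axial loss; with the default geometry none of
  the canonical frequencies is resonant.
- A source polarised so that it couples to no mode in the set is an error,
  not a zero field; numerically negligible couplings (symmetry zeros) are
  clamped to zero so they cannot seed noise.
- Tone offsets must lie inside the receiver band and outside the declared
  image band at synthesis time; extraction inside the image band warns.
- PCA uses a deterministic sign convention (largest-magnitude loading
  positive); regression de-means everything and falls back to the
  pseudo-inverse on rank-deficient designs with a warning; the separating
  plane falls back from hard-margin SVM to a least-squares discriminant
  with zero margin when the classes overlap, and reports leave-one-out
  accuracy as the separability score (a reproducible surrogate for a
  plane drawn by eye).
- CSV round trips are exact: doubles are written with 17 significant
  digits and parsed with base R's correctly rounded reader.
- Problem sizes in tests and examples (15–21 sweep offsets, 16-point
  quadrature cap, 8–30 s physiological records, 115 + 50 MIMO frames) were
  chosen so the full suite exercises every pipeline end to end in about a
  minute; all are configuration parameters, and the defaults above are the
  study conditions.

## Storage

A simulation run is a plain-text directory: the scenario config (YAML), the
raw acquisition (long-form CSV plus a JSON header with dimensions, dwell
time, line times, bands and tone table), flux/trace/truth CSVs, an analysis
`report.json`, and exactly one `manifest.json` (command, config hash, seed,
package version, timestamp) so every output is regenerable. There is no
binary container; an HDF5-style hierarchy is mirrored by the directory
layout instead, which keeps runs diffable and dependency-free.

## Known limitations

The modal bore model omits the body entirely, so absolute modulation levels
are not transferable to in-vivo settings; phase results are model-defined
(no AM–PM); third- and higher-order intermodulation has no power law (only
the polynomial tool); the separating plane is linear only; and the MIMO
response surfaces, while seeded and smooth, are synthetic — conclusions
about real head-coil geometry require measured calibration data.
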