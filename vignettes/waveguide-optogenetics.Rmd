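---
title: "Evanescent-field optogenetics on polymer waveguides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evanescent-field optogenetics on polymer waveguides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

photonstim analyses a biohybrid stimulation platform: neurons expressing
channelrhodopsin-2 (ChR-2) grow directly on low-index-contrast polymer rib
waveguides in aqueous medium, and the evanescent tail of the guided
~490 nm light opens the channels of exactly those cells that touch the
waveguide. This vignette explains the models behind each module, the
tunable parameters and their defaults, what the synthetic-data generators
do and do not emulate, and the numerical choices that matter.

## 1. Evanescent optics

A guided mode with effective index $n_\mathrm{eff}$ bounded by a cladding
of index $n_c$ decays above the surface as $I(y) = I_\mathrm{surf}
e^{-y/d_p}$ with

$$ d_p = \frac{\lambda}{4\pi\sqrt{n_\mathrm{eff}^2 - n_c^2}} . $$

The $4\pi$ (not $2\pi$) makes $d_p$ an *intensity* decay length, the
convention used for 1/e penetration depths in TIRF microscopy. Objective
TIRF is the same formula with $n_\mathrm{eff} = n_i \sin\theta$. Two
derived quantities matter for stimulation:

* `threshold_height(I_surf, I_th, d_p)` $= d_p\ln(I_\mathrm{surf}/I_\mathrm{th})$,
  the height at which the intensity falls to the ChR-2 activation
  irradiance (≈5 mW/mm²). With the default rib this is ≈620 nm at 1 mW
  guided power.
* `min_input_power_mW(I_th, I_surf per mW)`: surface intensity scales
  linearly with guided power, so the smallest power that still reaches the
  threshold at the surface is their ratio — ≈15 nW for the default rib.
  We deliberately expose the linearly scaled value rather than asserting
  any externally quoted figure for this quantity.

**Medium conversion.** A depth measured in one medium (an index-matched
sucrose solution, default $n = 1.450$) is restated for water ($n = 1.340$)
by holding the tangential wavevector $\beta/k_0 =
\sqrt{(\lambda/4\pi d_p)^2 + n_{c,\mathrm{meas}}^2}$ fixed — the guided or
reflected wave does not depend on which medium its tail is probed in. Two
consequences worth knowing: conversion to a lower index always *shrinks*
$d_p$, and a water-referred depth is only reachable from a measurement
medium whose index is below $\beta/k_0$. A water-referred 80 nm depth
implies $\beta/k_0 = 1.426$, which is *below* 1.450 — such a measurement
cannot have been made in a 1.450 medium, so the objective-TIRF 80 nm
synthetic case is generated directly in water. `convert_penetration_depth`
refuses impossible conversions with a no-evanescent-regime error and
always reports the indices used.

Defaults that are design choices (all configurable): fused-silica
substrate $n = 1.463$ at 491 nm (Malitson dispersion), sucrose $n = 1.450$
(matched to silica beads), angles in degrees, vacuum wavelengths in nm.

## 2. Slab dispersion and the mode solver

`slab_neff()` solves the standard three-layer asymmetric slab relation by
bracketing the monotone dispersion function on 1000 initial intervals and
bisecting to $10^{-9}$ in $n_\mathrm{eff}$ — deterministic, no seeds. It
returns `NA` with status `"cut off"` below cutoff (the default 40 nm
residual slab alone is far below the ≈113 nm TE0 cutoff, which is what
confines light laterally to the rib).

`solve_modes()` is a semi-vectorial scalar-Helmholtz finite-difference
solver: the operator $\nabla_t^2 + k_0^2\varepsilon(x,y)$ is discretised
with the 5-point stencil on a cell-centred grid (Dirichlet boundaries) and
its top eigenpairs are obtained by shift-invert Lanczos (sparse Cholesky of
$\sigma I - A$ with $\sigma = k_0^2 n_\mathrm{core}^2$, ARPACK iteration).
For TE-like modes the dominant (lateral) E-field is tangential to the
horizontal interfaces that dominate this low, wide rib, so the scalar
approximation with *area-averaged permittivity* at interface cells is
appropriate; cell averaging restores near-second-order convergence at the
index steps.

Numerical choices:

* Window 9 µm × 4 µm with 1.5 µm of substrate; the solver refuses windows
  that pad the rib by less than 2 µm laterally or 1.5 µm above.
* Grid 50 nm (x) × 10 nm (y). The discretisation is second order in the
  vertical spacing; at 10 nm a further halving moves the TE00 effective
  index by less than $10^{-4}$ (at 20 nm it moves by $1.1\times10^{-4}$,
  which is why 10 nm is the default). One solve of the default problem
  (72k unknowns) takes well under a second.
* Surface intensity: profiles live at cell centres, so the first
  pure-cladding row is extrapolated back to the interface with the mode's
  own decay constant before taking the line maximum. The reported value is
  the maximum along the surface line (for these symmetric modes it sits
  above the rib centre anyway).
* `mode_penetration_depth()` fits the log-intensity tail above the surface
  and cross-checks against the closed form from $n_\mathrm{eff}$; the two
  must agree within 10% and the fit must have $R^2 \ge 0.99$, otherwise a
  diagnostic warning is attached.

For the default geometry the solver gives $n_\mathrm{eff} = 1.5104$,
$d_p = 56.1$ nm (TE00, with < 3% spread across TE00/TE10/TE20 — the rib is
so low that all three modes press equally against the top surface) and a
surface power density of $3.3\times10^5$ mW/mm² per mW guided power.

**Edge coupling.** `gaussian_overlap()` propagates a Gaussian beam (waist
at the fiber facet, 1/e² intensity diameter = mode field diameter, default
4.5 µm to match the rib width; gap medium air by default) across the gap
with the standard $w(z)$, $R(z)$ beam laws and evaluates the normalized
power-overlap integral
$\eta = |\iint E_1E_2^*|^2 / (\iint|E_1|^2 \iint|E_2|^2)$ at optimal
lateral alignment, reporting $10\log_{10}\eta$. The Gaussian norm is taken
analytically ($\pi w_0^2/2$) so window truncation of the beam tails cannot
inflate the result; Fresnel reflection is excluded. The gap-propagation
machinery is verified against the closed-form coupling of two identical
Gaussian beams, $\eta = 1/(1+(z/2z_R)^2)$, to better than 0.01 dB.

A caveat the tests make explicit: for this thin (340 nm) mode against a
4.5 µm beam the ideal overlap is ≈ −6.0 dB in contact and −6.3 dB at a
10 µm gap. The vertical mismatch dominates; no beam of MFD ≥ 2.8 µm can
couple better than −3.6 dB to this mode, and the best overlap over *all*
waists is ≈ −3.2 dB near $w_0 \approx 0.8$ µm. Externally quoted coupling
figures for this geometry that are markedly higher than −6 dB cannot be
reproduced by the stated overlap integral with the stated beam.

## 3. Bead calibration

The calibration bead (silica, 7.38 µm, FITC-coated) rests on the surface;
fluorophores on its lower hemisphere at lateral distance $r$ from the
contact point sit at height $y(r) = R - \sqrt{R^2 - r^2}$. Near the
contact point $y \approx r^2/2R$, so the evanescently excited cap is an
almost perfect Gaussian spot of width $\sqrt{R\,d_p}$ (≈0.46 µm here) —
which is why a 2-D Gaussian fit localizes the centre to well under 0.1 px.
The pipeline is:

1. `fit_bead_center()`: 2-D Gaussian least squares (Levenberg–Marquardt via
   minpack.lm) around the brightest smoothed pixel; localization fails if
   the fitted amplitude is below 3× the robust background noise SD or not
   significant against its own standard error (blank frames).
2. `pixel_heights()`: sphere-geometry height map, pixels at $r \ge R$
   masked invalid. Pixel coordinates are 0-based with centres at integer
   coordinates.
3. `fit_penetration_depth()`: nonlinear least squares of
   $I(y) = A e^{-y/d_p} + b$ over $y \le$ 500 nm (the default cap keeps the
   fit 6–9× the expected depth while avoiding the equator region where the
   height error diverges). Initialisation $A = \max$, $d_p$ = 100 nm,
   $b$ = 5th percentile. At least 30 valid pairs are required; a relative
   standard error above 50% or a height span under $2 d_p$ flags the fit
   unreliable.
4. `convert_penetration_depth()` to water. The conversion never touches the
   medium-frame fit; both values are reported.

Counts are assumed proportional to excitation intensity (equal collection
efficiency for all fluorophores, no depth-dependent correction) — the same
simplification the measurement itself relies on. When the bead sits on the
waveguide edge only a stripe of it is excited (the excited cap turns
elliptical); supplying a `stripe_mask` restricts the fit to those pixels,
which on synthetic data changes the estimate by far less than its standard
error because the height-to-count relation is unchanged, only the sampling
of heights is.

## 4. Response mapping

Movies follow the stimulation protocol: `background_s` of baseline
(default 20 s), then `n_pulses` (10) at `pulse_rate_hz` (1 Hz) with 60 ms
width, 60 s total, sampled at 10 Hz. Pulse $i$ fires at
$t_i = \mathrm{background} + i/\mathrm{rate}$, i.e. the default train
spans 21–30 s: the standard 21–31 s analysis window then contains exactly
ten stimulation periods, making the ideal windowed response periodic —
this is the only clock for which the textbook picture of "distinct peaks
at integer multiples of 1 Hz" holds exactly, and it is why that window was
chosen in the first place.

Per pixel, `harmonic_response_score()` evaluates the unnormalized DFT of
the raw windowed trace at the bins of harmonics 1–5 of the stimulation
frequency and sums the magnitudes. Conventions, fixed and documented
rather than guessed: raw (one-sided, unscaled) magnitudes, no window
taper, no detrending; the DC bin is excluded, which makes the score
invariant to any constant offset (exactly in exact arithmetic; floating
rounding leaves ~$10^{-13}$ relative). Every requested harmonic must fall
exactly on a DFT bin — the call is refused otherwise, naming the offending
harmonic — and the final map divides by the field-of-view maximum, so the
map is invariant to any global intensity scale (and to the one-sided vs
raw amplitude convention). The single-trace and whole-movie paths share
the same direct DFT arithmetic, so the map equals the pixel-wise score to
the bit; an independent fft()-based oracle agrees to $10^{-9}$ relative.

The responder threshold (0.5 of the normalized score) is a classification
utility parameter, never baked into any report. On pure noise the
normalized scores cluster near half the maximum, so thresholded counts are
meaningless there; the right null check — implemented in the tests —
compares the *raw* score distribution against a frame-order permutation of
the same movie.

## 5. Cut-back loss budget

`cutback_fit()` is ordinary least squares of total transmission (dB,
losses negative) on straight-waveguide length (cm): the slope is the
propagation loss, the intercept collects facet coupling and bends.
`decompose_intercept()` subtracts `n_facets × coupling` (coupling enters
as a measured constant with its uncertainty propagated in quadrature) and
divides the remaining bend loss by a user-supplied turn count — the turn
count is required input because it is a property of the spiral layout, not
of the fit. With 6 devices the residual degrees of freedom are 4, so
confidence intervals use Student's t; a ±2·SE rule would cover only ~88%
and is not what the package tests. Two distinct lengths give exact
interpolation with undefined SEs, flagged as such.

`payne_lacey_loss()` implements the published upper bound for scattering
from a rough slab surface, $\alpha_\mathrm{max} = \kappa\,\sigma^2/(k_0
d^4 n_1)$ with $\kappa \approx 1$ and $d$ = half the core thickness. This
bound is the maximum over roughness correlation lengths; the supplied
correlation length (default 50 nm, exponential autocorrelation) is
validated and recorded but cannot lower the bound. At $\sigma = 5$ nm the
bound is ≈65 dB/cm — one to two orders above measured losses, as upper
bounds of this kind usually are; the result is explicitly tagged
order-of-magnitude and should never be read as a prediction.

## 6. Synthetic data: what it emulates, what it does not

The generators define the study conditions under which every recovery test
runs:

* **Bead images**: expected counts $\mathrm{peak}\cdot e^{-y(r)/d_p}$
  inside the projected disc (peak 2.5e3 counts at the contact point,
  pixel 0.129 µm ≈ a 132 µm field on 1024 px), optional excitation stripe,
  then noise.
* **Calcium movies**: flat baseline of 5000 counts; each pulse adds
  $\mathrm{baseline}\cdot\Delta F/F_0\cdot e^{-(t-t_i)/\tau}$ to responder
  pixels ($\Delta F/F_0 = 0.3$, $\tau = 0.5$ s — typical Rhod-3 scales,
  both exposed). Responders are all cell pixels (full-field mode) or the
  pixels of cells intersecting the 4.5 µm stripe (waveguide mode). The
  default frame is 1200×1200 px; tests and the analysis scripts use the
  128×128 fast mode. Scene layouts redraw (inside the seeded stream) until
  at least one soma straddles the stripe, because the waveguide experiment
  by construction images a field with neurons on the waveguide.
* **Camera noise**: Poisson shot noise on expected counts, Gaussian read
  noise (SD 5 counts, sCMOS-scale), offset 100 counts, rounded and clamped
  at zero; a fully noiseless model returns exact expectations unrounded.
  The baseline/noise levels were fixed from a signal-to-noise feasibility
  estimate of the harmonic score (signal bins scale with baseline, noise
  bins with its square root) before any acceptance test was run.
* **Cut-back tables**: $T = \mathrm{slope}\cdot L + \mathrm{intercept} +
  \mathcal N(0, 0.3\ \mathrm{dB})$ over lengths 1.2–8.1 cm.

Every generator returns a machine-readable ground-truth record including
its seed; identical seeds give bit-identical output, and the generators
restore the caller's RNG state.

Not emulated — so passing tests say nothing about these aspects of real
data: optical PSF blur (no convolution), photobleaching (none generated,
an optional linear detrend exists behind a flag and is off by default),
spontaneous activity (off by default; a Poisson-timed transient flag
exists), neurite morphology, motion, fluorophore photophysics, and
spectral cross-talk between the opsin and the calcium dye.

## 7. Problem sizes and limitations

The shipped tests and scripts use the 128×128 (movies) and 64×64 (pipeline
round-trips) frames, 20 noise seeds for bead recovery, 10 seeds for
response maps, and 1000 replicates for cut-back CI coverage; these sizes
were chosen so the whole suite exercises every claim in minutes while
keeping Monte-Carlo bands comfortably tighter than the assertions.

Known limitations: the mode solver is scalar (no vectorial corrections to
$d_p$, no Goos–Hänchen shift, no bend modes); grating couplers are out of
scope entirely; the bead model ignores collection-efficiency variation
with height; the response mapping performs no spike inference and no
motion correction; and dB bookkeeping throughout uses signed values with
losses negative.
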