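---
title: "Methods: passive spectroscopy and guided-wave dispersion in blood vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive spectroscopy and guided-wave dispersion in blood vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexwave)
```

## The physical picture

A blood vessel guides elastic waves. Treating the vessel as a hollow
elastic cylinder, two branches propagate at cardiac frequencies: the
longitudinal L(0,1) mode — an axisymmetric diameter expansion, the
classical pulse wave — and the flexural F(1,1) mode — a lateral flexion
of the whole tube with no cross-sectional change. The first is fast and
nearly non-dispersive at these frequencies; the second is slow and
strongly dispersive, with phase velocity growing like the square root of
frequency × diameter. Both are driven naturally: the heartbeat is an
axisymmetric pressure source, and any ambient motion couples into
flexion. `flexwave` measures both from recordings and computes the
corresponding theory.

Two measurement settings are supported.

* **Intensity movies** (retinal scale): a bright vessel in a
  power-Doppler-like image sequence. Wave passage modulates the
  on-vessel intensity. Averaging each cross section suppresses the
  axisymmetric contribution (the average of an equal-and-opposite
  pattern across the lumen is zero), so this channel predominantly sees
  the flexural wave — one reason a slow wave dominates retinal
  measurements.
* **Two-wall displacement records** (carotid scale): wall positions
  tracked along the imaging beam. Expansion moves the two walls in
  opposite directions, flexion moves them together, so the half-sum
  and half-difference isolate the antisymmetric and symmetric fields
  exactly (`separateModes()`), whatever their spectra.

## Passive spectroscopy

The estimator is built for *uncontrolled* sources. Given one trace per
curvilinear abscissa, Φ_x(t), each trace is Fourier transformed and only
the **phase** is kept. The monochromatic focal spot at frequency f is

$$C(f, r) = \left\langle \cos\!\big(\arg\hat\varphi_s(f) -
\arg\hat\varphi_{s+r}(f)\big)\right\rangle_s ,$$

averaged over all source positions s such that both s and s + r lie in
the record (pairs leaving the vessel are simply dropped; near the ends
fewer pairs contribute). Discarding the modulus whitens the spectrum and
makes the correlation self-normalized: multiplying Φ by any positive
envelope leaves C unchanged, which matters because vessel brightness is
never uniform. For a single unidirectional plane wave, phase differences
are exactly k·r and C(f, r) = cos(2πr/λ) at machine precision — the
module's primary correctness anchor, enforced in the tests at 1e-10.

**Wavelength fit.** λ is obtained by nonlinear least squares of
C(r) = cos(2πr/λ) around the central peak. The window runs between the
first negative-going zero crossings on either side of r = 0 when both
are visible; otherwise the full aperture is used. The second case is
essential at carotid scale, where the symmetric wavelength (tens of
centimeters) far exceeds the 4 cm aperture: the fit then extrapolates
from the curvature of the central lobe. The initial value is 4× the
first zero-crossing lag, or 8× the aperture when no crossing is
visible; bounds are [2 grid steps, 1000 apertures] and a fit landing on
a bound is reported as a failure, never as a wavelength. A flat
correlation (single position, silent band) raises an explicit error
rather than returning λ = ∞.

**Frequency selection.** Analysis frequencies are the local maxima of
the position-averaged magnitude spectrum above a relative prominence
threshold (default 0.1) — the harmonics of the cardiac comb. Peak
localization uses a 4× zero-padded FFT; a Hann window is applied for
*peak picking only*, because padding an unwindowed spectrum resolves
the rectangular-window sidelobes of each harmonic into spurious local
maxima (at −13 dB they would pass any reasonable prominence threshold,
while Hann sidelobes at −31 dB do not). Focal spots themselves are
computed on the raw, unpadded, unwindowed grid; the wavelength fit
happens in the lag domain and is independent of this choice.

**Assembly.** v = λ·f is enforced exactly when the dispersion curve is
assembled; the uncertainty is propagated as σ_v = f·σ_λ, neglecting the
frequency error, which is appropriate for records synthesized or
measured with bin-aligned harmonics. Failed frequencies are flagged
(`fitOk = FALSE`), never dropped silently.

**Broadband variants.** The polychromatic focal spot is the
spectral-magnitude-weighted average of monochromatic spots over a band;
widening the band suppresses side lobes while the central peak keeps
the central wavelength. The central frequency of a broadband mode is
measured from the temporal autocorrelation: the lag of the first local
maximum after the first zero crossing, refined parabolically.

## Correlation time of flight

As an independent cross-check, `tofMap()` computes, for each spatial
separation Δx, the time cross-correlation of the trace pair, averaged
over all source positions, after making each trace zero-mean and
unit-energy so bright segments do not dominate. A traveling wave gives
a ridge Δt = Δx/v. `tofVelocity()` extracts, per time lag, the spatial
lag of maximum correlation (3-point parabolic interpolation; lags whose
maximum sits at the aperture edge or below a correlation threshold are
rejected), then fits a weighted line **through the origin** — a wave
passes Δx = 0 at Δt = 0 by construction — with bisquare reweighting
against outliers at large lags. For a dispersive field the number is a
band-average velocity and is labeled as such; it is expected to fall
between the phase velocities at the band edges, which the tests check
on flexural synthesis. The default time-lag window is half the dominant
period, so the ridge of a periodic field cannot wrap onto the next
cycle.

Directional filtering (2-D FFT, zeroing the two quadrants whose
spatial × temporal frequency sign corresponds to the rejected
direction, keeping the shared axis bins) suppresses reflected waves.
It is only applied when at least one wavelength fits inside the
aperture: beyond that the propagation direction is spatially
unresolvable — the wave's energy sits in the lowest spatial-frequency
bins — and quadrant zeroing distorts the field instead of cleaning it.
The carotid pipeline makes this decision per mode from the fitted
wavelength.

## Guided-wave theory

The dispersion relation of a traction-free hollow cylinder is the
vanishing determinant of the boundary-condition matrix built from
Helmholtz potentials: a compressional potential solving a Bessel
equation with radial wavenumber α² = ω²/c_L² − k², and two shear
potentials with β² = ω²/c_T² − k² (orders n+1 and n under the gauge
H_r = −H_θ). Stress rows (σ_rr, σ_rθ, σ_rz at the inner and outer
radii) act linearly on the radial functions and their first
derivatives; the radial functions are J/Y where the wavenumber squared
is positive and modified I/K where it is negative — the generic case
here, since vessel waves travel far below both bulk velocities. For
n = 0 the longitudinal block is the 4×4 system (σ_rr, σ_rz rows;
compressional and order-1 shear columns); the torsional block is
decoupled and not solved. For n = 1 the full 6×6 matrix is used.

Numerical conditioning is dominated by the contrast c_L/c_T ≈ 4300:
matrix entries span many orders of magnitude. Each column is normalized
to unit maximum magnitude before the determinant — column scaling moves
the determinant's value but not its zeros — and the root search never
evaluates exactly at a bulk velocity, where a radial wavenumber
degenerates.

**Root finding.** At fixed frequency the determinant is scanned over
phase velocity in a ±50 % window around a seed; a sign change brackets
the root, which Müller's three-point quadratic iteration then polishes
(secant fallback on a degenerate parabola; bisection fallback if the
iterate leaves the bracket). The search is in velocity at fixed
frequency, not wavenumber at fixed velocity, because the target curves
are v(f). Seeds come from the low-frequency limits; at subsequent grid
points the previous root is carried forward, rescaled by the
low-frequency law between the two frequencies so that coarse grids
stay inside the bracketing window. This continuation selects the first
branch and rejects higher ones. Halving the scan step moves converged
roots by well under 0.1 %.

**Low-frequency limits.** The package provides three closed forms:

* `vLpwLowfreq()` — the symmetric plateau √3·c_T (the bar velocity of
  an incompressible wall, independent of geometry);
* `vFpwBeam()` — the exact flexural limit: the Euler–Bernoulli bending
  wave of a beam with the tube's annular cross section,
  v = √(ω·√3 c_T·r_g), r_g = √(a² + b²)/2 the radius of gyration
  (outer radius a, inner radius b). The numerical F(1,1) branch
  converges to this expression (ratio 0.9999 at 0.1 Hz at the reference
  geometries), and it seeds the solver;
* `vFpwLowfreq()` — the simpler engineering form √(π f d c_T/√3),
  which shares the √(f·d) scaling but uses a cruder prefactor tied to
  the outer diameter alone. It differs from the exact limit by a
  constant factor of ~1.3–1.5 depending on wall thickness. It is kept
  as the package's reference dispersive law for synthesis (any
  √f law exercises the estimators equally) and for quick desk
  arithmetic.

Because both closed flexural forms scale as √f, their ratio to the
numerical branch is frequency-independent at low f; only `vFpwBeam()`
has ratio → 1. At the reference retinal parameters (wall thickness
15 µm, c_L 1500 m/s, c_T 0.35 m/s) the computed F(1,1) branch spans
~1–25 mm/s from 0 to 10 Hz at a 60 µm outer diameter, and ~1–34 mm/s at
100 µm; the corresponding symmetric plateau is ≈ 606 mm/s. Below
~0.05 Hz at micrometer geometries the determinant's conditioning
degrades (Bessel arguments ~10⁻³ and K-functions very large), which
shows as a ~0.1–1 % wobble in the recovered root; the convergence tests
therefore probe 0.1–0.4 Hz rather than arbitrarily small frequencies.

**Moens–Korteweg.** PWV = c_T·√(3h/d) with exact inverse
c_T = PWV/√(3h/d), and μ = ρc_T². Inverting a 620 mm/s symmetric PWV at
h = 15 µm gives c_T between 0.72 (d = 60 µm) and 0.92 m/s (d = 100 µm)
— reported as a bracket, since the appropriate diameter within a real
measurement is itself uncertain.

## The synthetic-data generator

Synthesis is exact in the frequency domain: a mode is a superposition
of traveling cosines, each harmonic f_k propagated with wavenumber
2πf_k/v(f_k) in the mode's direction. There is no PDE solve — the
analysis itself treats the field as a superposition of harmonic modes,
so the generator produces precisely the structure the estimators
assume, which is what makes exact oracles possible. By default the
fundamental is snapped to an FFT bin of the record so every harmonic
completes an integer number of cycles (no spectral leakage); a flag
(`binAlign = FALSE`) disables this for leakage-robustness studies.

Scenario defaults are the study conditions of the two settings:

* **retinal** — 38 Hz frame rate, 5.3 mm field of view, a ~1.5 Hz
  cardiac fundamental with six equal harmonics (the harmonic amplitude
  profile of a real cardiac source is not prescribed; equal amplitudes
  exercise every analysis frequency equally), one antisymmetric mode
  following the √(f·d) law at the 100 µm reference geometry, rendered
  as intensity modulation on a gently curved bright vessel (Gaussian
  transverse profile) over a dark background, 16 s record,
  48 × 192 pixels;
* **carotid** — 500 Hz frame rate, 4 cm aperture, 128 positions, 2 s
  record (1000 frames), a non-dispersive symmetric mode at 3.4 m/s and
  antisymmetric mode at 0.5 m/s, driven by harmonics 3–12 of 1.5 Hz so
  the band (≈4.5–18 Hz) matches the 6–19 Hz range where carotid central
  frequencies are observed.

Noise is additive Gaussian on intensity or displacement, parameterized
by the amplitude signal-to-noise ratio (default SNR 10); there is no
speckle model, no flow model, and no imaging physics (holography or
beamforming) — the generator emulates the statistical structure the
analysis consumes, not the instrument. Consequently, passing tests
demonstrate the correctness and noise robustness of the estimators on
fields with the assumed structure; they do not certify performance
against speckle decorrelation, clutter, tracking artifacts, or
reflected waves in real recordings. Rendering clamps intensities at
zero, but the default background sits ≳4 noise standard deviations
above it, so the clamp is inactive in practice and rendering stays
linear in the fields. All randomness derives from a single integer
seed; identical seeds give bit-identical outputs.

## Geometry extraction

Segmentation of the time-averaged image uses a Sobel gradient magnitude
with an Otsu threshold (both overridable — neither an optimal threshold
nor the original median-line construction is prescribed anywhere, so
both are exposed as parameters). The edge mask is restricted to the
connected component containing the seed point (or the largest); a
comparably sized component running alongside it is adopted too, because
the two wall rails of a clean vessel are disjoint edge curves. The
centerline is the sequence of midpoints between paired opposing edges
scanned along the vessel's long axis, smoothed with a 5-point moving
average, and resampled by linear interpolation to a uniform abscissa
step of one pixel pitch. Tangents come from centered differences on the
smoothed centerline; cross sections are sampled perpendicular to them
with bilinear interpolation (one sparse matrix applied to all frames),
and averaged over a half-width defaulting to half the measured local
lumen width. A per-trace linear detrend removes slow acquisition
drifts, which do not carry wave information. Reversing the centerline
orientation flips x but leaves every wavelength estimate unchanged
(cosines are even), which is tested.

## Numerical choices and degenerate inputs

* Focal spots snap requested frequencies to the nearest FFT bin,
  warning if the snap exceeds a quarter bin; a band or bin with no
  spectral energy (relative floor 1e-10 of the spectrum maximum) is an
  error, not a silent fit to numerical noise.
* `tofVelocity()` requires at least 4 ridge points above the
  correlation threshold (default 0.25) and rejects argmaxima at the
  aperture edge; an absent ridge is an error.
* The carotid pipeline declares a mode "below the noise floor" when its
  energy falls under 1e-3 of the stronger mode's, rather than fitting
  noise phases.
* Mode separation uses the factor ½ so outputs are per-mode
  displacement amplitudes; an imaging plane misaligned with the flexion
  plane scales the antisymmetric amplitude (modeled via an optional
  gain in `renderWalls()`) but cannot affect the wavelength, and the
  estimators are amplitude-invariant anyway.
* All file interfaces are SI; human-readable reports convert to mm/s
  (retinal) or m/s (carotid) with explicit unit strings, and every
  reported velocity carries a method tag (`spectroscopy` or `tof`).

## Problem sizes

The default test and example configurations — 48 × 192 × 608-frame
movies, 128 × 1000 wall records, 20-point theory grids with 81-point
velocity scans — were chosen as the smallest sizes at which every
estimator operates in its intended regime (≥ 6 harmonics below Nyquist,
wavelengths both under and over the aperture, ≥ 100 correlation pairs
per lag). The full suite runs in under a minute on one core.

## Known limitations

* The tube model is empty and in vacuo: blood loading and surrounding
  tissue, both of which slow the waves, are not modeled — the theory
  curves are upper bounds for in vivo velocities, and a quantitative
  in vivo inversion would need a fluid-loaded, embedded-tube model.
* Only the first branches L(0,1) and F(1,1) are computed; torsional
  modes and higher branches are out of scope.
* The time-of-flight estimate on a dispersive band mixes phase and
  group effects; it is reported as a band-average and should be read as
  a consistency check, not a dispersion measurement.
* The segmenter assumes one dominant, roughly ridge-like vessel; it is
  not a vascular-tree segmentation tool, and arteries are not
  distinguished from veins.
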