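---
title: "Methods: ratiometric plasmonic detection and sizing of single vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric plasmonic detection and sizing of single vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panorama)
```

# The measurement model

A gold-nanodisk array supports a localized surface plasmon resonance
(LSPR): a peak in the extinction spectrum whose position moves linearly
with the local refractive index,

$$\lambda_{\mathrm{peak}}(n) = \lambda_0 + S\,(n - n_0),$$

with bulk sensitivity $S$ in nm/RIU. The package's defaults are the
measured operating values of the sensor this pipeline targets:
$\lambda_0 = 659$ nm at $n_0 = 1.00$ (air) and $S = 242.42$ nm/RIU, so
the water-immersed peak sits at 739 nm. Illumination passes a 660/10 nm
bandpass filter, i.e. the band sits on the steep short-wavelength
shoulder of the water-immersed resonance. A particle binding to the
surface raises the local index, red-shifts the resonance away from the
band, lowers in-band extinction, and therefore *increases* transmission
at the particle's position: in the ratio of a sample frame to a
particle-free background frame (the intensity-ratio or IR image), the
particle is a bright spot with $\mathrm{IR} > 1$.

`transmission_ratio()` makes this quantitative:

$$\mathrm{IR}(\Delta n) =
\frac{\int_{\mathrm{band}} \left[1 - E(\lambda;\ \lambda_{\mathrm{peak}} + S\,\Delta n)\right]\mathrm{d}\lambda}
     {\int_{\mathrm{band}} \left[1 - E(\lambda;\ \lambda_{\mathrm{peak}})\right]\mathrm{d}\lambda}.$$

Three modeling choices here were genuinely open and are worth recording:

* **Lineshape.** The extinction curve $E(\lambda)$ is a Lorentzian on a
  flat baseline — the standard single-resonance plasmon model, and
  analytically convenient (closed-form half-maximum, symmetric tails).
  Nothing downstream depends on the tails beyond the band integral.
* **Band profile.** The filter is modeled as a top-hat of the stated
  center and FWHM, integrated by the trapezoidal rule at 0.1 nm steps
  (the tests check agreement with an independent 0.01 nm quadrature to
  1e-6). The true filter profile is not specified by its part number
  alone, and a 10 nm-wide band averages over profile details anyway.
* **Resonance linewidth.** The FWHM default of 120 nm is not a measured
  value; it was chosen once so that the 660 nm band sits on the steep
  left shoulder of the 739 nm water peak, which is the stated operating
  geometry. It affects only the forward model, not detection.

The forward model is used for physical plausibility (monotonicity of IR
in $\Delta n$, recovery of $S$ from simulated two-media peak
measurements), **not** to render images. There is no established mapping
from one bound vesicle to an effective $\Delta n$ at the hot spot, so
the synthetic generator drives pixel brightness directly from contrast
via the size calibration (below). This keeps the generator's ground
truth exact by construction.

# Detection

For each sample frame:

1. **Registration.** Integer-pixel alignment to the background by
   exhaustive normalized cross-correlation within ±`max_shift` (default
   5 px); a best correlation under 0.5 is an alignment failure.
   Sub-pixel registration is deliberately omitted: bound particles are
   immobilized, drift between frames is small, and pixel-level
   precision is what the ratiometric step requires.
2. **Ratiometric image.** Pixelwise division; background pixels below
   1% of the background median are masked (guards against dead pixels
   and division blow-ups), and more than 10% masked pixels is treated
   as a degenerate input rather than silently analyzed.
3. **Noise estimate.** $\sigma$ is the standard deviation of background
   IR values. Since particles contaminate a sample IR image, the
   default estimator is robust: $1.4826 \times \mathrm{MAD}$ after
   discarding the brightest 0.5% of pixels. On a particle-free image
   this agrees with the plain standard deviation to a few percent (a
   tested property). A second mode estimates $\sigma$ from an IR image
   of two particle-free background frames instead
   (`sigma_mode = "background"`); which population the "background IR
   values" should be in routine use is ambiguous, so both are
   implemented and the sample-frame mode is the default.
4. **Threshold.** $\mathrm{IR} = 1 + 3\sigma + 0.005$. The absolute
   margin of 0.005 dominates false-positive control: at the default
   noise level the threshold sits roughly $6\sigma$ into the Gaussian
   tail, and the test suite verifies zero false calls on more than
   $10^7$ pure-noise IR pixels.
5. **Particle calling.** Connected components of supra-threshold pixels
   with 8-connectivity and a 2-px minimum area (suppresses single-pixel
   noise hits; both values configurable). The component labeling is
   implemented as a union-find over the sparse foreground and is
   checked against a brute-force flood-fill oracle on randomized
   images.
6. **Contrast.** Per particle, $(\mathrm{IR}_{\mathrm{peak}} - 1)
   \times 100\%$ using the component's **peak** pixel. Peak rather than
   mean preserves the size encoding of a sub-diffraction particle under
   the PSF: the peak of the Gaussian footprint carries the particle's
   full contrast, while the component mean depends on how much of the
   skirt clears the threshold. Mean aggregation remains available
   (`contrast_stat = "mean"`).

For pixel-centered noiseless particles the detected contrast equals the
injected contrast exactly; for sub-pixel positions point-sampling of the
PSF loses at most a factor $\exp(-0.25/\sigma_{\mathrm{psf,px}}^2)$
($\approx 0.73$ at the default PSF width), a bound the tests assert.

# Sizing and classification

Contrast maps to diameter through the empirical quadratic

$$Y = 0.153\,X^2 + 7.096\,X + 20.211$$

($X$ contrast in %, $Y$ diameter in nm), strictly increasing for
$X \ge 0$ and inverted in closed form by the positive quadratic root
(round-trip tested to 1e-9). The calibration was regressed against
nanoparticle tracking analysis on exosome-scale particles; the package
flags contrasts outside $[0, 30]\%$ as extrapolation but still computes
them.

Classification uses the inclusive disjunction: sEV if contrast
$< 18\%$ **or** diameter $< 200$ nm, both strict. Because diameter is a
strictly increasing function of contrast and $Y(18) = 197.51 < 200$,
the diameter clause is the weaker one and the effective boundary is
$Y^{-1}(200) = 18.196\%$ contrast; a particle at exactly 18% is
therefore an sEV through the diameter clause. Both component flags are
recorded per detection so either convention can be recovered from the
output.

Summaries report mean and *sample* ($n-1$) standard deviation — the
convention that reproduces the replicate statistics this pipeline is
expected to produce (e.g. counts {1553, 1451, 1647} give 1550 ± 98) —
with single-detection sets flagged rather than given an undefined sd.

# The synthetic generator

`simulate_binding()` + `make_series()` produce ground-truthed series
emulating a push-pull incubation experiment:

* **Binding kinetics.** Each candidate particle binds at an
  exponentially distributed waiting time (first-order rate constant),
  truncated to the incubation window; unbound candidates are dropped.
  The observed cumulative counts are therefore non-decreasing by
  construction, and the empirical binding-time distribution is tested
  against the closed-form truncated CDF. This is a phenomenological
  model chosen for its single interpretable parameter — no
  convection–diffusion transport is simulated. The default rate
  constant 0.023/min binds ~75% of candidates within 60 min, giving
  the steady accumulation shape seen in real runs.
* **Wash.** Survival of the buffer rinse is Bernoulli per particle.
  Retention is exposed as a free parameter (default 0.575, a typical
  observed retained fraction) rather than asserted, because the washing
  physics is not modeled.
* **Rendering.** The noiseless frame is
  `background_level × texture × Π(1 + (c/100)·G)`: multiplicative
  Gaussian footprints (sd $0.21\lambda/\mathrm{NA} \approx 146$ nm
  ≈ 0.9 px at the default 0.1625 µm/px scale, a 6.5 µm camera pixel
  behind a 40× objective) on a smooth multiplicative fixed-pattern
  texture (sd 2%, correlation length ~20 px). Multiplicative footprints
  are what the transmission-enhancement picture implies, and they make
  the ratiometric step cancel the texture exactly in the noiseless
  limit — an additive model would not preserve the IR-contrast
  definition under background structure.
* **Noise.** Zero-mean Gaussian per pixel with sd
  `per_frame_noise_sd / sqrt(frames_averaged)` of the mean level,
  emulating 100-frame averaging at 30 ms exposure. The default
  per-frame sd of 1.18% is derived backwards from the operating point:
  an IR image divides two averaged frames, compounding their noise by
  $\sqrt{2}$, so the background IR sd is
  $\sqrt{2} \times 0.0118/10 \approx 0.00167$ and the full threshold
  excursion $3\sigma + 0.005 \approx 1\%$ — the background noise level
  a stable flow cell holds throughout a run. Whether that quoted ~1%
  refers to $\sigma$, $3\sigma$, or the full excursion is ambiguous;
  the generator assumes the full excursion and the detector estimates
  $\sigma$ from data regardless, so the choice only sets the simulated
  operating point.
* **Drift.** Optional rigid integer-pixel translation of sample frames,
  exercising the registration stage round-trip.
* **Determinism.** One integer seed drives every draw; series and
  on-disk runs are byte-reproducible (tested via file checksums).

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: plasma-matrix background (lipoprotein
and protein adsorption), region-dependent capture efficiency along the
channel, mass-transport limitation, particle aggregation, non-Gaussian
or skewed contrast distributions, photobleaching-free but
non-stationary illumination, and any deviation of true vesicle optics
from the quadratic calibration. The tests certify the *algorithmic*
contract (thresholding statistics, recovery of injected ground truth,
calibration arithmetic), not biological sensitivity or specificity.

# Aggregation across time and runs

Cumulative counts link detections across before-wash frames by greedy
nearest-centroid matching within 2 px (ties by distance, then detection
id) — bound particles do not move, so persistence matching prevents a
particle that straddles the threshold in one frame from being counted
twice. Raw per-frame counts are reported alongside, and a raw-count
decrease between before-wash frames raises a data-quality warning
rather than an error. Wash analysis reports the after-wash count, the
retained fraction of the final before-wash count (an undefined-fraction
sentinel when the denominator is zero), and after-wash summaries.
Replicate summaries (mean, $n-1$ sd) require at least two runs.

Counts are reported as integers, means and sds to 2 decimals, fractions
to 3 — the precision at which such runs are compared in practice.

# Problem sizes and runtime choices

The defaults describe the full 200 µm × 200 µm field (1231² px). The
test suite exercises the identical code paths on 256² px sub-fields
(and 1600² px fields for the false-positive census, totaling over
$10^7$ background pixels), with particle densities near the real runs'
~0.04 particles/µm² — sizes chosen so the whole suite runs in well
under ten minutes on one CPU while keeping every statistical check
meaningful.

# Interfaces

Camera frames travel as 16-bit grayscale TIFF, IR images as 32-bit
float TIFF (stored at half scale, which is exact in binary floating
point for IR < 2, to respect the unit-range float TIFF convention;
rescaled transparently on read), detections and ground truth as CSV,
run reports as JSON with the full configuration and its MD5 hash
embedded. The command-line entry point (`inst/cli/panorama.R`) is a
thin wrapper over `simulate_run()`, `detect_run()` and `report_runs()`
with subcommands `simulate`, `detect` and `report`; all logic lives in
the package functions, so everything the CLI does is testable in-process.

# Known limitations

* No sub-pixel localization or deconvolution; centroids are
  intensity-weighted at pixel resolution.
* Merged detections: two particles closer than the footprint diameter
  (~5–6 px) are called as one component. At realistic densities this
  affects a few percent of calls; the cumulative-by-matching counter
  mitigates double counting but cannot split merges.
* The calibration is taken as given; no uncertainty is propagated from
  its coefficients, and extrapolation beyond ~300 nm is flagged but not
  prevented.
* The binding model is first-order and spatially homogeneous; it cannot
  reproduce inlet-to-outlet capture gradients.
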