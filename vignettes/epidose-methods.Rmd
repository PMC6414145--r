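---
title: "epidose: model, assumptions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epidose: model, assumptions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the physical model implemented by `epidose`, the
parameters it fixes, the design decisions that shaped the implementation, and
the limitations of the synthetic-data approach. Quantitative statements here
are restricted to quantities computed by the test suite or by
`scripts/acceptance.R`.

## 1. Signal model

The detector signal behind an object of water-equivalent thickness `t` (cm)
at pixel position `(x, y)` is modelled as

```
I = I0(x, y) · Φ(x, y) · exp(−α·t − β·t²) · (1 + k0·A·t) ,
```

with

* `I0` — the open-field signal of the calibration geometry, measured per
  pixel (no flat-field idealisation);
* `Φ` — the relative beam fluence of the treatment field (1 inside a flat
  aperture, 0 outside; a wedge is a linear ramp, 0.5 → 1.0 across the field);
* `exp(−α·t − β·t²)` — a quadratic-exponent primary attenuation term; the
  quadratic term absorbs beam hardening, so `α` and `β` are empirical
  per-pixel calibration coefficients rather than narrow-beam attenuation
  coefficients;
* `(1 + k0·A·t)` — a first-order scatter-to-primary ratio (SPR),
  proportional to the irradiated field area `A` (cm²) at the isocentre plane
  and to the object thickness, with `k0 = 1.93e-5 /cm³`.

Acquisition is frame-integrated: a delivery of `n_frames × frame_time`
(default 60 × 430 ms ≈ 25.8 s, i.e. a 100 MU exposure) averages the
instantaneous image over the frame midpoints while the phantom follows a
motion trace, applies optional multiplicative Gaussian noise per frame
(default relative SD 0.005), and adds a dark-current offset (default 100
counts). The noise level is a package choice — the source analysis gives no
noise model — set so that repeat static acquisitions agree well within 1%.

## 2. Calibration

`fit_quadratic()` fits, per pixel, `−ln(I_t / I0) = α·t + β·t²` over a slab
series (default thicknesses {0, 2, 4, 7, 11, 16, 21} cm) by linear least
squares with no intercept; `I0` comes directly from the measured `t = 0`
member. Because the design matrix `(t, t²)` is shared by all pixels, the
normal equations are solved once and applied as vectorised map algebra.
Pixels with any non-positive signal, or a non-positive fitted `α`, are
flagged invalid rather than silently used.

Two properties matter downstream:

* On noiseless scatter-free data the fit is exact (recovery to 1e-8 across
  `(α, β) ∈ [0.03, 0.08] × [0, 5e-4]`; acceptance test 2).
* When the calibration series itself contains the `(1 + k0·A_cal·t)` scatter
  term, the fitted `α` *absorbs* `ln(1 + k0·A_cal·t)` (approximately linear
  in `t` over the calibrated range). The fitted coefficients are therefore
  effective coefficients of the calibration geometry, not the generating
  ones. This is by construction, and it is why the parameter-recovery tests
  generate their series with `k0 = 0`, while the forward/backward consistency
  test (section 3) uses fully scatter-consistent data.

## 3. Thickness reconstruction

`invert_quadratic()` solves the quadratic in closed form, taking the root
branch that is non-negative for attenuated signals, with a linear fallback
for `|β| < 1e-9`, clamping `I ≥ I0` to `t = 0`, and returning `NA` for
non-positive signals or negative discriminants.

`reconstruct()` wraps the inversion in the field-size/scatter correction
loop. Each pass (i) inverts the calibration for the current estimate `t_i`
and (ii) rebuilds the corrected intensity

```
I_{i+1} = (I / F) · (1 + k0·A_cal·t_i) / (1 + k0·A_treat·t_i) ,
```

then re-inverts. Two design decisions here were forced by divergence
analysis rather than taste:

* **The correction is applied to the original image each pass, not to the
  previous iterate.** A literal compounding recurrence
  `I_{i+1} = I_i · (1+SPR_cal)/(1+SPR_treat)` multiplies a ratio > 1 onto the
  signal every pass and grows without bound — the reconstruction collapses.
  Re-evaluating the factor at the current `t` and applying it to the original
  dark-corrected, F-normalised image makes the loop a fixed-point iteration
  (a contraction in `t`), which settles in five passes on the noiseless
  synthetic breast image (acceptance test 1: `max|Δt| < 0.01 cm` within 5
  iterations).
* **The output factor `F = open_treat / I0` divides the treatment image.**
  `F` is a per-pixel image ratio, so besides the field-size output change it
  carries any static fluence modulation (the wedge). Dividing by `F` moves
  the treatment image onto the calibration intensity scale; multiplying
  (the other reading of "corrected by F") would square the wedge profile
  instead of removing it. The choice is verified by the test in which a
  wedged uniform slab reconstructs flat only when `F` divides.

The fixed point agrees with an independent scalar root-finder on the full
forward curve (`uniroot`, tolerance 1e-12) and, end-to-end, reconstructing a
noiseless static acquisition recovers the phantom thickness to well below
0.05 cm RMS inside the field (`thickness_rms_error_cm` in
`results/acceptance.json`).

## 4. Synthetic phantom and motion

The phantom is an analytic thickness function (not a voxel grid), so motion
is exact resampling rather than interpolation of a discretised object:
a `cos²`-profile dome (the breast) on a broader `cos²` chest mound, with the
apex thickness equal to the prescribed maximum separation (default 16 cm,
range restricted to the calibrated (0, 21] cm). The analytic form keeps
adjacent-pixel thickness steps below 0.5 cm at 256 × 256 / 0.1 cm, so the
gamma distance search operates on smooth data.

Motion is one-dimensional along the image x axis. Traces are:

* sinusoids `A·sin(2π·f/60·t + φ)` with amplitude in cm and frequency in
  cycles/min, matching how programmable motion platforms are specified;
* patient-like irregular breathing: built cycle by cycle, period and
  amplitude drawn per cycle from lognormal distributions with configurable
  coefficients of variation, a flattened-exhale cycle shape
  `A·sin(π·u^1.4)⁴`, and optional linear baseline drift. Fully deterministic
  in its seed.

The delivery starts at a seeded random offset into the trace (an arbitrary
respiratory phase), so repeated "deliveries" of the same trace differ — as
they would clinically.

## 5. Segmentation and ROI

The radiation field is segmented by thresholding at a fraction of the robust
(99th-percentile) maximum, keeping the largest 8-connected component
(`EBImage::bwlabel`), and tracing the outer boundary with a Moore-
neighbourhood Freeman chain code (8 directions, clockwise scan from the
backtrack direction, Jacob's stopping criterion). The experiment uses a
threshold fraction of 0.1 rather than the generic 0.5 default: behind a
wedge plus 16 cm of attenuating phantom, in-field signal drops to roughly a
fifth of the open-field maximum, and a 0.5 threshold would cut the field
interior rather than its edge.

The breast ROI mimics an operator-drawn polygon: the phantom's breast
outline is converted to pixel coordinates and filled with an even-odd
scanline algorithm (pixel centres on the boundary included; self-
intersecting polygons rejected; zero-area polygons flagged degenerate), then
intersected with the field mask.

## 6. Dose comparison

Thickness maps are mapped to a relative dose surrogate with fixed conversion
coefficients (`α = 0.05 /cm`, `β = 1e-4 /cm²`), so maps from different
sessions are compared on a common scale. Two metrics:

* `dose_diff_summary()`: per-pixel local relative difference
  `(D_eval − D_ref)/D_ref`, reported as the percentage of ROI pixels within
  ±5, 3, 2, 1%.
* `gamma_2d()`: local-dose 2D gamma. For each ROI pixel `r`,
  `γ(r) = min_p sqrt(|p−r|²/d² + (D_eval(r) − D_ref(p))²/(0.01·c·D_ref(p))²)`
  over search positions `p`, with the dose criterion `c`% normalised to the
  reference dose *at the compared position* (local normalisation). The
  search covers a disc of radius `search_factor × d` (default 3) on a
  sub-pixel grid (`pixel_pitch / interp_factor`, default 1/10 pixel) with
  the reference bilinearly interpolated on the fly. Offsets are scanned in
  increasing distance so the scan stops once the pure distance term exceeds
  the current minimum. Requesting a native-grid search with a distance
  criterion below the pixel pitch is an error (undersampled search), not a
  silent degradation.

Implementation notes that came out of testing rather than design:

* Bilinear samples on a grid line adjacent to out-of-field (`NA`) reference
  pixels must not be poisoned by the zero-weight `NA` corner (IEEE
  `0 × NA = NaN`); the C++ kernel skips zero-weight corners. Without this,
  identical images produced nonzero gamma along the field edge.
* The truncation radius is part of the operation's contract. The acceptance
  comparison against an exhaustive brute-force oracle therefore widens
  `search_factor` until the disc covers the whole test patch; with the
  default radius, gamma values are exact below `search_factor` and clipped
  above it.

`gamma_2d()` agrees with an independent exhaustive fine-grid oracle to
within 0.05 γ on uniform-offset, shifted-edge and blurred-dome cases at all
four criteria (acceptance test 4).

## 7. Experiment design and expected behaviour

`default_experiment_config()` encodes the packaged study: a wedged 14 × 8
cm² field, 26 × 26 cm² flood calibration, sinusoid amplitudes
{0.5, 1.0, 1.5} cm × frequencies {12, 15, 20} cycles/min, one
1.5 cm / 18 cycles/min sequence, and two patient-like traces, all at
256 × 256 / 0.1 cm. Seeds are derived deterministically (calibration
`seed+1000`, treatment open field `seed+2000`, sequence `i` `seed+10·i`),
so sequences have independent noise but the whole experiment is reproducible
from one integer.

The computed trends (acceptance test 5 and `results/acceptance.json`):
2%/2 mm gamma pass rates are monotonically non-increasing in sinusoid
amplitude over {0, 0.5, 1.0, 1.5} cm at 12 cycles/min, and the pass-rate
spread across frequencies at fixed 1.0 cm amplitude is far smaller than the
spread across amplitudes — motion amplitude, not frequency, drives the
dosimetric effect of blurring for a static aperture (there is no interplay
effect without beam-aperture motion). A zero-amplitude "motion" acquisition
is bit-identical to the static one at the same seed, giving γ ≡ 0 and 100%
within every threshold (acceptance test 6).

## 8. Problem sizes

On the development container (single CPU): the full 256 × 256 experiment
with six motion sequences plus the static reference runs in well under a
minute; `scripts/acceptance.R`, which additionally runs the calibration
noise study and the gamma oracle comparison, completes in tens of seconds;
the complete test suite runs in about a minute.

## 9. Limitations

* **Synthetic data only.** The simulator is self-consistent with the
  reconstruction model (same attenuation law, same first-order SPR), so
  end-to-end accuracy statements validate the *implementation*, not the
  physical model. Against a real EPID the quadratic-exponent/linear-SPR
  model is an approximation, and residual errors would be larger.
* The SPR model is first-order in `t` and linear in field area, with a
  single geometry-dependent constant `k0`; detector-plane scatter kernels,
  off-axis spectral variation and support-arm backscatter are not modelled.
* Motion is rigid 1D translation of the thickness function; no deformation,
  no out-of-plane motion, no aperture motion (hence no interplay effect).
* The dose surrogate is attenuation-derived relative intensity, not a
  dose-to-water calculation; gamma and dose-difference results compare
  sessions, they do not verify absolute dose.
* Patient-like traces are a stylised generator (lognormal cycle statistics,
  fixed cycle shape); they are not recorded respiratory signals.
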