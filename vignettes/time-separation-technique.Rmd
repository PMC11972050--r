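---
title: "Time separation reconstruction of dynamic perfusion scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time separation reconstruction of dynamic perfusion scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tstperf)
```

## The reconstruction model

A dynamic perfusion acquisition on a C-arm system samples each projection
angle once per sweep, at a view-specific time. The reconstruction problem
`A v(t) = p(t)` is therefore badly undersampled in time: with eight to
ten sweeps there are only that many samples of any projection pixel's
time course. The time separation technique restores tractability by a
low-dimensional temporal model: voxel TACs and projection-pixel time
series are expanded in a common orthonormal basis of `N` temporal
functions, which turns the time-dependent problem into `N` independent
static tomographic problems — one reconstruction per basis function,
regardless of how densely the time axis is sampled afterwards. The model
assumes (i) contrast dynamics throughout the organ lie close to the span
of the basis, (ii) the projection operator is time-invariant (no motion),
and (iii) each pixel's samples are dense enough for the per-pixel least
squares fit (at least `N` valid samples; pixels below that are flagged
invalid and imputed from the nearest valid angle, never silently zeroed).

Two basis families are provided. The analytical set
`{1, sin(2*pi*t/T), cos(2*pi*t/T), sin(4*pi*t/T), cos(4*pi*t/T)}` needs no
prior data; its constant term models the static anatomy, the harmonics
the washin/washout. The prior-knowledge set extracts the leading temporal
modes of a previously acquired time-resolved series by SVD of the
organ-masked voxels-by-time matrix, with series first aligned in time at
their AIF peaks and resampled to the span of the shortest scan. The
number of retained modes is capped at the singular-spectrum elbow and
fixed at four by default: four modes are what a liver perfusion scene
(background + parenchymal washin + hypo-perfused washin + arterial bolus)
genuinely spans, and fits with many more functions than samples per pixel
become unstable.

Orthonormality is defined with trapezoidal quadrature weights on the
dense sample grid (0.1 s by default, an order of magnitude finer than any
view spacing). This is a deliberate numerical choice: under the plain
endpoint-inclusive dot product the trigonometric set retains O(1/K)
spurious Gram off-diagonals (about 3e-3 on a 0.1 s grid), while the
trapezoidal product makes periodic trig integrals exact to machine
precision. SVD modes, orthonormal under the plain product, are passed
through a weighted QR so that every basis delivered to fitting satisfies
one single orthonormality contract; on a uniform grid this rotation is
negligible (it touches only the two endpoint weights).

### Time alignment

Bolus arrival differs between subjects and scans, so a basis may need to
be shifted in time before fitting, by the difference of AIF peak times.
Two regimes follow: scan times that fall outside the shifted basis
support are excluded from the per-pixel fits (the projections are
dropped, the basis kept intact), and a basis longer than the scan is
simply cropped, with the offsets recorded. Cropping destroys
orthogonality; both paths are provided — fitting with the raw cropped
basis (default, keeps the prior-knowledge shapes untouched; least squares
does not require orthonormality) or explicit re-orthonormalization via
`reorthonormalize()`, which preserves the span but rotates the functions.

## The synthetic study

The phantom stands in for a reprojected CT perfusion scan: a 2D
elliptical organ (64 x 64 at 3 mm, a 192 mm field) of healthy parenchyma
containing an embolized disk and a feeding artery. Each region follows a
gamma-variate enhancement over a static baseline,
`amp * ((t-t0)/(alpha*beta))^alpha * exp(alpha - (t-t0)/beta)`, peaking at
`t0 + alpha*beta`. Defaults, chosen once as a realistic arterial-phase
liver scene: artery `t0 = 5.5 s, alpha = 3, beta = 1.8 s` (peak 10.9 s,
peak enhancement 0.012/mm), healthy tissue `t0 = 7 s, beta = 3 s`
(peak 16 s, 0.004/mm), embolized tissue at one fifth of the healthy
amplitude with delayed, dispersed kinetics (`t0 = 8.5 s, beta = 4.5 s`) —
hypo-perfusion reduces and retards flow, which is what makes the
embolized region separable in BF, MTT *and* TTP rather than amplitude
alone. Voxel amplitudes are jittered by 5% (seeded) for within-region
texture. The phantom's time grid spans 42 s at 1 s spacing, the duration
of the shortest reference scan the prior-knowledge basis is meant to
cover.

The acquisition simulator follows the experimental C-arm protocol: eight
contrast-enhanced sweeps of 248 views over 200 degrees, 3.9 s rotation,
1.4 s pause, rotating alternately forward and backward (backward sweeps
reuse the reversed forward angle list, so no angle inconsistency is
simulated). Frame times follow a trapezoidal gantry-velocity profile
(default acceleration fraction 0.15 of the sweep at each end; the
protocol documentation states only that gaps widen at the sweep ends, so
the profile shape is a package choice, exposed as a parameter). Photon
noise is Poisson in the count domain: `I ~ Poisson(N0 exp(-p))` with
`N0 = fluence x detector bin area` and `p' = ln(N0 / max(I, 1))`; the
stated fluence is interpreted as unattenuated flux, the bin area comes
from the projector spec (a 3 mm desk-scale bin integrates more photons
than a 0.16 mm physical detector pixel, which keeps the relative noise
physically comparable), and zero-count bins are floored at one count.
Fluence presets: "high" 2.1e5, "moderate" 6e5 photons/mm^2.

What the phantom does *not* emulate: realistic vascular trees,
portal-venous inflow, scatter, detector lag, organ truncation, intestinal
motion, or the forward/backward angle inconsistency of a real C-arm.
Passing the synthetic study therefore demonstrates the correctness and
the noise/undersampling behavior of the algorithms, not clinical
performance.

## Reconstruction and numerical choices

The projector is an explicit sparse system matrix (Joseph ray-driven line
integrals, parallel or fan 2D geometry), so the adjoint is exact by
construction and any conforming linear operator could replace it; the
separation mathematics never looks inside `A`. All reconstructions use
unregularized CGLS (default 50 iterations or relative residual 1e-6; a
residual rising over five consecutive iterations aborts with
diagnostics). An optional nonnegativity clamp applies to static sweep
reconstructions only. Static sweep volumes are stamped at mid-sweep time:
treating a sweep's views as simultaneous cannot localize dynamics better
than the sweep midpoint, and this choice is what produces the
characteristic late AIF peak of roughly half a sweep duration that the
pipeline reports.

Perfusion maps use truncated-SVD deconvolution of the single-voxel AIF
(highest peak, ties to the earliest peak then lowest index; ROI averaging
is available but off by default). TACs are resampled by Akima splines to
100 uniform points across the supported interval and baseline-subtracted
(the first synthesized value per voxel; sweep-wise reconstructions
subtract the first, mask, sweep). Akima interpolation is implemented in
the package: it passes through the samples, reproduces linear data
exactly, and — unlike a natural cubic spline — does not overshoot between
samples of step-like data, which matters when resampling TACs with sharp
bolus fronts. The truncation threshold keeps singular values strictly
greater than `lambda_rel * sigma_max` with `lambda_rel = 0.3`; the value
at the threshold is zeroed. The convolution matrix carries the time-step
factor by default (`dt_scaling = TRUE`) so that BF (1/s), BV (unitless)
and MTT (s) are unit-consistent and stable under grid refinement; an
unscaled mode reproduces the plain discrete-sum convention, and
`MTT = BV / BF` holds exactly in both. Voxels with nonpositive BF get an
undefined MTT and are excluded from smoothing and evaluation masks rather
than zero-filled. Maps are smoothed slice-wise by a mask-normalized
Gaussian (sigma 3 px) so background never bleeds across the organ edge.

Evaluation reports masked Pearson correlation per slice and pooled over
all masked voxels; the pipeline summary uses the pooled value (a single
number is reported even though the computation is slice-wise; both are
kept, and the report says so). Noise is estimated as the median absolute
deviation of the finest-scale diagonal Haar wavelet details divided by
0.6745 (Donoho's robust estimator), averaged over slices, using only 2x2
blocks fully inside the mask.

## Determinism and problem sizes

A single top-level seed drives the run; each stochastic stage receives a
derived sub-seed (`100 * seed + offset`, logged in the report), so
reports are bit-identical across reruns and stages are independent of
unrelated configuration blocks. The shipped study sizes — 64 x 64 grid,
8 x 248 views, 100-point TAC grids — were chosen so the complete
pipeline, including both reconstructions and all maps, runs in seconds on
one CPU while keeping the tomographic sampling (91 detector bins, 200
degrees) non-trivial.

```{r example, eval = FALSE}
cfg <- read_pipeline_config()
cfg$noise$fluence_per_mm2 <- "high"
res <- run_pipeline(cfg, out_dir = "run")
res$report$pearson
```

## Known limitations

* Desk-scale 2D geometry; cone-beam 3D would need only a conforming
  projector, but none is bundled.
* The prior-knowledge refinement of the mode count against reference
  perfusion maps requires reference scans and is out of scope; the mode
  count is the elbow estimate capped by configuration (default 4).
* Automatic AIF localization and basis-shift estimation in the
  projection domain are not implemented; shifts are explicit inputs.
* No motion correction: the separation model assumes a static organ, and
  violations contaminate the fitted coefficients before reconstruction.
* Deconvolution near the acquisition start is limited by the
  baseline-subtraction convention: the AIF's first sample is zero by
  construction, so the convolution matrix is singular in its last
  column and the final kernel sample is unrecoverable (irrelevant for
  BF/BV/MTT at 100-point grids).
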