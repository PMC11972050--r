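# tstperf

Model-based reconstruction of dynamic (CB)CT perfusion scans with the
**time separation technique (TST)**, together with a fully synthetic
desk-scale acquisition simulator, for researchers working on C-arm /
cone-beam CT perfusion imaging of parenchymal organs.

## The problem and the method

Interventional C-arm CT acquires a dynamic perfusion scan as a handful of
slow bidirectional rotations ("sweeps"): every projection angle is seen
only once per sweep, at a different time, so reconstructing each sweep as
if its views were simultaneous (static reconstruction) misplaces and
blurs the contrast dynamics, and cone-beam data are noisy to begin with.

The TST models every voxel TAC (time attenuation curve) and every
projection-pixel time series as a linear combination of a small
orthonormal temporal basis `{psi_1, ..., psi_N}`:

    v_nu(t)  = sum_i  w_{nu,i}  psi_i(t)
    p_n(t)   = sum_j  c_{n,j}   psi_j(t)

Inserting this into the time-dependent reconstruction problem
`A v(t) = p(t)` separates it into `N` *static* tomographic problems

    A w_i = c_i ,   i = 1..N,

solved here by CGLS. The per-pixel coefficients `c` are fitted by linear
least squares over each pixel's sample times (one per sweep per angle),
with the basis resampled by Akima splines at the exact nonuniform frame
times. The basis is either the analytical trigonometric set
`{1, sin(2*pi*t/T), cos(2*pi*t/T), sin(4*pi*t/T), cos(4*pi*t/T)}` or a
prior-knowledge set: the leading temporal modes (right singular vectors)
of organ voxel TACs from a previously acquired perfusion series, with an
elbow rule on the singular spectrum and AIF-peak time alignment.

Perfusion maps follow by indicator-dilution deconvolution: for each voxel
`tac = aif * k`, the lower-triangular Toeplitz AIF matrix is inverted by
truncated SVD (singular values above `0.3 * sigma_max` kept), and

    BF = max(k),   BV = sum(k) dt,   MTT = BV / BF,   TTP = argmax(tac).

The package also ships a gamma-variate digital perfusion phantom
(healthy, embolized and arterial regions), a bidirectional multi-sweep
view scheduler with trapezoidal gantry-velocity frame times, Poisson
photon noise in the count domain, sweep-wise static reconstruction as the
comparator, and evaluation tools (masked Pearson map similarity,
wavelet-MAD noise estimation).

## Worked example

```r
library(tstperf)

cfg <- read_pipeline_config()          # bundled 8-sweep, 248-view protocol
cfg$noise$fluence_per_mm2 <- "high"    # 2.1e5 photons / mm^2
res <- run_pipeline(cfg, out_dir = "run")
cat(readLines("run/report.txt"), sep = "\n")
```

which prints (seed 1):

```
Perfusion pipeline report (seed 1)
  basis: prior_knowledge (4 functions); fluence: 210000; 1984 views over [0.00, 41.00] s
  AIF peak: truth 10.77 s, TST 10.77 s, static 12.44 s (static delay 1.68 s; half sweep 1.95 s)
  pooled Pearson vs ground truth        sigma (noise sd)
  map    TST      static                TST      static
  BF      0.9997   0.6232            1.565e-05 8.541e-05
  BV      0.9999   0.9975            0.0001312 0.0001923
  MTT     0.9971  -0.6476             0.001635  0.01023
  TTP     0.9996   0.9131             0.001341 0.004209
```

Reading: with a 4-function prior-knowledge basis the TST maps stay almost
perfectly correlated with the ground-truth maps and carry several times
less estimated noise than the sweep-wise static reconstruction, whose AIF
peak is also displaced late by roughly half a sweep duration — the three
qualitative signatures that motivate model-based perfusion
reconstruction. All intermediates (schedule CSV, basis CSV, NIfTI map and
series volumes, JSON report) are written to `run/`.

A thin shell entry point with the same behavior is installed at
`inst/cli/tstperf` (subcommands `pipeline`, `schedule`,
`basis-analytical`).

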