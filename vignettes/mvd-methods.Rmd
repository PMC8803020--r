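---
title: "Multi-view deconvolution methods: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view deconvolution methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Light-sheet fluorescence microscopy images a specimen plane-by-plane with
orthogonal illumination and detection. Two physical limitations shape the
raw data: the resolution along the detection axis is several-fold worse
than the lateral resolution, and emitted light is scattered and absorbed on
its way to the camera, so deeper regions are dimmer and blurrier. Rotating
the specimen about a fixed (vertical) axis and acquiring several views —
here four, at 90° steps — places every structure close to some camera and
turns each view's poorly resolved axis into another view's well-resolved
one. Multi-view deconvolution (MVD) fuses the registered views into a
single volume with near-isotropic resolution.

`mvdeconv` implements three MVD variants on registered, isotropic, cubic
volumes whose rotation axis is the y (second array) index:

* **3D MVD** — joint Richardson-Lucy (RL) deconvolution of the full
  volumes with per-view 3D PSFs; the quality reference, and the most
  expensive.
* **2D MVD** — RL fusion applied independently to every x–z plane
  (perpendicular to the rotation axis) with 2D PSFs; cheap, but blind to
  intensity redistributed along y.
* **2D+1D MVD** — 2D MVD followed by a 1D RL deconvolution of every
  y-column with the 1D PSF along the rotation axis; nearly as cheap as 2D
  MVD and much closer to 3D quality.

The 2D and 1D PSFs are the central x–z plane and the central y-column of
the 3D PSF (`extract_psf2d()`, `extract_psf1d()`). When the 3D PSF is
exactly separable into that plane and column, convolving slice-wise with
the 2D PSF and then column-wise with the 1D PSF reproduces the 3D
convolution exactly; this is the regime in which 2D+1D and 3D deconvolution
agree, and one of the package's acceptance properties checks it
numerically.

## The update rule

One RL iteration for a single view `i` with forward projector `f` (the
PSF) and back projector `b` is

    e <- e * ((i / (e * f)) * b)        ("*" = convolution)

For several views with per-pixel fusion weights `w_v` the package computes
all per-view corrections `c_v = (i_v / (e * f_v)) * b_v` from the current
estimate and applies their weighted average in one multiplicative step:

    e <- e * (1 - sum_v w'_v + sum_v w'_v * c_v)

where `w'_v` are the weights after multiplication with the apodization
mask. Where the mask is 1 the weights sum to one and the update is the
plain weighted-average RL step; where the mask rolls off to zero the update
blends toward a no-op, so apodization damps the iteration rather than
draining intensity. This form was chosen over a sequential per-view loop
because (a) it reduces exactly to classical RL for one view or any number
of identical views, (b) a view with zero weight at a pixel contributes
nothing there, and (c) its per-iteration step size matches classical RL,
which puts the practically relevant operating range (quality optimum
within roughly 5–15 iterations, over-iteration artifacts beyond) at the
same iteration counts a user of the reference 3D method would expect.
The iteration starts from the voxel-wise average of the (masked) views.

Numerical guards: values of the blurred estimate `e * f` below `1e-12`
(intensities are on a `[0, 1]` scale) are treated as zero and replaced by
one before the division, and negative excursions of the FFT-computed
correction are clamped to zero, so every estimate is nonnegative.

## Back projectors

`make_backprojectors()` offers three choices:

* `matched` — the axis-mirrored PSF of the same view; classical RL.
* `opt1` — each view's mirrored PSF convolved with all other views' PSFs.
* `opt2` — a single compound kernel, the inverse transform of the
  product of all views' OTFs, shared by all views.

The compound kernels spread each view's correction into the directions the
other views constrain, which shifts the quality optimum to fewer
iterations; run past the optimum they amplify artifacts, which is exactly
the over-iteration degradation the quality curves show. Compound kernels
are cropped to the smallest odd bounding box that keeps at least
`1 - 1e-6` of their mass (per-axis marginal tail bound), then
renormalized; without the crop the 4-view compound support would roughly
quadruple the FFT grid in every axis for a negligible change in the
kernel.

The default (`backprojector = "auto"`) resolves to `opt2` for the fast
slice-wise methods — acceleration is their reason to exist — and to
`matched` projectors for the 3D reference. A compound back projector is a
poor fit for the 3D reference under a separable PSF: its width along the
rotation axis smooths exactly the y-corrections that distinguish 3D MVD
from the slice-wise approximations, and the 3D method's role here is the
classical quality benchmark, which also matches its later iteration
optimum (8 versus 5). Any explicit choice applies to all methods.

## Weighting and masks

Because scattering and absorption differ between views, each voxel is
fused with per-view weights (`weights_entropy()`, default, or
`weights_intensity()`). Entropy weighting computes the local variance
`sigma^2` over an 11 x 11 pixel patch (mirror-padded, population variance)
and uses `H = 1/2 ln(2 pi e sigma^2)` as a contrast proxy; the weight of a
view is its fractional contribution to the entropy sum over views. The
variance is clamped below at `1/(2 pi e)` so `H >= 0`: the fractional
weighting would be ill-defined with negative entropies, the clamp
preserves the ordering of informative patches, and flat patches get zero
weight. Pixels where no view has information get uniform weights `1/N`.
Weights are computed once per slice from the registered input views, not
recomputed per iteration — they describe the views, not the estimate.

Two apodization masks suppress FFT edge artifacts: `binmask()` (the
blurred OR of the views' supports, Gaussian sigma 20 px) acts in-plane and
is applied to data and weights once before iterating and once to the final
estimate; `blend1d()` (Gaussian sigma 5 px) apodizes the y-columns before
1D deconvolution, with the content range determined once per volume (first
to last y-slice with content). The 3D variant's mask is the per-slice
binmask additionally multiplied by the blend profile along y, because the
3D convolutions also see the y-boundaries; the slice-wise variants never
transform along y. On small test volumes (64^3) the sigma-20 blur is wide
relative to the field and the mask is visibly below one even at the
center; this affects all variants identically and cancels out of
comparisons.

## Acquisition simulator

`simulate_multiview()` emulates the conditions the deconvolution is meant
for, so every stage is testable without external data:

* **Ground truth** — `make_lines_phantom()`: rays from the volume center
  in uniformly random directions with an anti-aliased 1-voxel FWHM
  profile plus a brighter central body (a microtubule-aster-like object,
  thin structure in every orientation); `make_bead_phantom()`:
  well-separated single-voxel impulses with known centers for resolution
  analysis.
* **Views** — the phantom is rotated into the view frame (exact 90°
  permutations; arbitrary angles are out of scope), attenuated
  exponentially with depth from the camera-facing face
  (`exp(-d/length)`, Beer-Lambert; default length half the extent —
  strong enough that opposite views differ materially, as in deep-tissue
  imaging), convolved with an anisotropic Gaussian PSF (default sigmas
  1.05 voxels lateral, 5.2 axial — FWHM about 2.5 and 12 voxels, i.e.
  about 2 and 10 µm at 0.806 µm voxels, mirroring a light-sheet
  detection PSF with ~5x axial/lateral anisotropy), degraded with Poisson
  noise (`counts ~ Pois(budget * I)/budget`, default budget 1000 photons
  at unit intensity) and additive Gaussian detector noise (variance
  1.6e-5 on the `[0, 1]` scale), clipped at zero, and rotated back so the
  views arrive registered.
* Per-view noise streams are seeded independently (`seed + view index`);
  everything is bit-reproducible for a fixed seed.

What the simulator does *not* model: spatially varying or non-separable
PSFs, registration errors, excitation-side stripe artifacts, and
depth-dependent PSF broadening. Passing tests on these fixtures therefore
demonstrate the correctness of the algorithms under the stated forward
model, not robustness to real-microscope imperfections — in particular,
with an exactly separable Gaussian PSF the quality gap between 2D+1D and
3D MVD is intrinsically small, whereas measured PSFs (non-separable,
tilted side lobes) widen it.

## Evaluation machinery

Quality against ground truth is tracked per iteration (`quality_curve()`)
with the mean squared error — after scaling the estimate by its
least-squares gain against the ground truth, since deconvolution does not
fix the absolute scale — and the (scale-free) Pearson correlation
coefficient as the cross-check. For the 2D+1D curve the fixed number of 1D
iterations (default 3) is appended to the 2D result at every iteration
depth, so its iteration index counts 2D sweeps.

Bead-based resolution follows the standard recipe: local-maxima detection
above a relative threshold with greedy separation pruning
(`detect_beads()`), per-axis FWHM from linearly interpolated half-maximum
crossings of background-subtracted profiles (`measure_fwhm()`; beads whose
profile is clipped at the volume edge are rejected), and a least-squares
cumulative-normal fit to the sorted FWHM samples (`fit_cumulative_normal()`)
whose location parameter and standard error summarize each axis. For
degenerate samples (e.g. noiseless fixtures where all beads are
identical) the fit falls back to the sample mean, flagged in the result.

## Operating point and problem sizes

Defaults follow the recommended operating point: 5 iterations for 2D MVD,
3 additional 1D iterations for 2D+1D, 8 iterations for 3D MVD, entropy
weighting with an 11 x 11 patch, the `"auto"` back projector (see above),
mask sigmas 20 (2D) and 5 (1D) pixels. `block_slices` controls how many x–z slices are
processed per scheduling block; blocking never changes results (the tests
assert bit-level equivalence up to floating-point associativity).

The packaged test suite and the acceptance script run the full pipeline at
reduced scale — quality curves on a 128^3 four-view fixture (attenuation
length 64), separable-PSF agreement at 64^3, bead analysis at 96^3 with 12
beads — sizes chosen so a complete run finishes in minutes on a single
CPU while preserving the PSF-to-volume proportions that make the
comparisons meaningful.

## Known limitations

* Rotations are restricted to multiples of 90°; registration of real
  multi-view data (and hence arbitrary-angle resampling) is out of scope —
  inputs are assumed registered.
* A single PSF per view, constant across the field of view.
* The FFT back end is single-threaded base R; the algorithms are
  structured around cached transfer functions per (shape, kernel) pair,
  which is where a GPU or threaded-FFT drop-in would attach.
* `tiff` stores samples as scaled integers; `write_volume()` records the
  intensity scale in a JSON sidecar and round-trips values to ~1e-9 of
  the intensity range (32-bit), which is quantization, not bit-exactness.
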