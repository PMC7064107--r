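---
title: "Limited-angle TXM reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limited-angle TXM reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Synchrotron transmission X-ray microscopy (TXM, "nano-CT") images a rotated
sample with parallel-beam soft X-rays. Flat samples on TEM grids cannot be
rotated past roughly ±50° without colliding with the zone plate, so only a
100° angular window is measured. Parallel-beam tomography needs 180° for a
complete dataset; the unmeasured 80° leaves a *missing wedge* in Fourier
space. By the microlocal picture of limited-angle tomography, only edges
whose normals fall inside the measured set of detector directions are stably
reconstructable — filtered back-projection (FBP) then shows streaks and
elongation in the missing directions. Cryo-immobilized cells add a second
problem: the ice layer holding the cell is laterally wider than the
field of view, so every projection is truncated and FBP exhibits a cupping
profile and a bright ring at the FOV boundary.

`laxm` implements this measurement model and two remedies end to end:
penalized weighted least-squares (PWLS) denoising of the log projections
before FBP, and a residual U-Net that predicts the artifact image of an FBP
slice so it can be subtracted.

# Forward model and units

Each ray measures a line integral of the attenuation map `f` (1/µm),

```
p(u, v, θ) = ∫ f dl,     p̂ = ln( N0 / max(I, 1) ),  I ~ Poisson(N0 e^{-p}),
```

with `θ` the sample rotation (z rotation axis), `u` the signed detector
coordinate and `v` the detector row. Parallel beams decouple the rows, so a
3D scan is a stack of independent 2D slice problems.

**Length unit.** Line integrals are accumulated with the *detector pitch*
as the unit of length, the convention of standard CT simulation toolkits.
FBP performed with the same unit returns `f` in 1/µm unchanged, so the
choice is self-consistent; what it fixes is the noise scale. With
attenuation values of a few 10⁻³–10⁻² 1/µm, physical micrometre path
lengths at a 21.9 nm pitch would give `p ≈ 0.03` (transmission 0.97) and
Poisson noise at `N0 = 10⁴` would drown every structure in the
reconstruction; with pixel-unit paths a through-cell ray has `p ≈ 1–4`
(transmission 2–40 %), which matches both realistic soft-X-ray
transmissions in the water window and the visible-but-not-dominant noise
level the method targets. Zero photon counts are clamped to one count
before the log.

Two projectors are provided behind the same interface. The *analytic*
projector sums the closed-form ellipse chord integrals
(`2ρAB√(a²−s²)/a²`) of every ellipsoid cross-section plus the exact chord
through the square ice slab; it is used for references and phantom scans.
The *discrete* projector is ray-driven (bilinear samples along each ray at
one-pixel steps) and handles arbitrary images; training corpora use it,
adding the closed-form chord of the slab part outside the image footprint.
Validation compares the two: away from rays tangent to a discontinuous
edge they agree to a fraction of a percent, and on a smooth-edged ellipse
(nested shells with a ramped boundary) the maximum relative error is below
1 % at the 256²-image / 512-detector scale. At a sharp edge itself no
pixel-basis image can reproduce the square-root singularity of the exact
sinogram; the deviation there (~3 % in a ±3-pixel band) is a property of
rasterization, not of the projector.

# The ellipsoid phantom generator

A phantom emulates a cryo-immobilized single cell: 2 large ellipsoids for
the outer boundary, 2 overlapping middle-sized ellipsoids approximating
the cup-shaped chloroplast (no boolean subtraction), 20 small lipid-body
ellipsoids and 50 small high-intensity gold fiducial particles, all inside
a constant 0.002 µm⁻¹ ice slab 1.5× wider than the FOV half-width (the
source of the truncation ring). Lipid and gold ellipsoids are placed by
rejection sampling (≤1000 attempts, then an error naming the category)
so they lie inside the outer boundary union; evaluation is exact
point-in-quadric arithmetic, never voxelized.

Intensity ranges (additive, 1/µm): outer 0.002–0.005, chloroplast
0.004–0.008, lipid 0.006–0.012, gold 0.015–0.020 — chosen so that summed
structures fill a [0, 0.02] µm⁻¹ display window with gold strictly the
brightest category. Semi-axis ranges as fractions of the grid: outer
0.28–0.42, chloroplast 0.12–0.20, lipid 0.02–0.05, gold 0.004–0.010. The
size fractions put the simulated cell at 6–9 µm across at the native
21.9 nm pitch — the upper half of the 2–10 µm range of chlorella — so the
cell fills most of the FOV. All ranges are configurable; every draw is a
pure function of the spec's seed.

What the generator does *not* emulate: non-ellipsoidal membrane shapes,
texture inside organelles, detector blur and zone-plate optics, scatter,
rotation-axis drift and jitter. Tests passing on these phantoms therefore
validate the reconstruction and learning machinery, not performance on
real TXM scans.

`surrogate_texture_images()` stands in for collections of
grayscale images of other modalities (optical-microscopy algae, medical
CT) that supply generic structure during training: each image mixes a
random low-order polynomial gradient, 8–23 random ellipses and rectangles,
and fine blurred-noise texture, rescaled to an attenuation range
(default 0–0.018 µm⁻¹). `load_gray_images()` swaps in real TIFF/PNG
collections when available.

# PWLS denoising

The denoiser minimizes

```
Φ(p) = Σ_i (p̂_i − p_i)²/v_i + β Σ_i Σ_{j ∈ N_i} w_ij (p_i − p_j)²
```

over the 4-neighbourhood `N_i`, with `v_i` an estimate of the per-pixel
noise variance and `w_ij` edge-preserving weights. The adopted forms are
`v_i = a e^{p̂_i/η}` (`a = 0.5`, `η = 1`) — the exponential mean–variance
relationship of log-transformed transmission data — and
`w_ij = exp(−(p_i−p_j)²/σ²)` with `σ = 2`; both are pluggable through the
config because only their shape, not their scale, is essential (the scale
is absorbed by `β`). The variance map is normalized to unit median so the
default `β = 1` balances data and penalty across photon levels; `β` itself
is exposed as the relaxation parameter.

The solver is exact per-pixel coordinate descent (Gauss–Seidel) in raster
order: `p_i ← (p̂_i/v_i + 2β Σ w_ij p_j) / (1/v_i + 2β Σ w_ij)`, which is
the coordinate minimizer of Φ as written (the neighbourhood sum counts
each pair from both sides). One "iteration" is one full sweep; the default
is two sweeps, with weights recomputed from the current estimate at each
sweep's start. With weights frozen, Φ is provably non-increasing — the
property suite asserts this on random instances. The 2D denoising unit is
the projection image at fixed angle; for single-slice sinograms each
projection is one detector row, so the neighbourhood degenerates to the
two u-neighbours.

# FBP discretization

The Ram–Lak ramp filter uses the standard spatial-domain taps (centre
`1/(4d²)`, odd offsets `−1/(π²n²d²)`, even offsets zero). Rows are
convolved by FFT after zero-padding to the next power of two ≥ 2× the
detector length, which confines circular wrap below the kernel tail; the
tap sum (the DC leak) decays as `1/(π²L)` and is verified against that
closed form. Backprojection interpolates the filtered row linearly at
`u = x cosθ + y sinθ` and integrates with weight Δθ (radians). The default
output grid is 256² from the 512-pixel detector (43.8 nm output pitch);
filtering stays at native detector resolution and no pre-binning is done.
The truncation ring is *not* masked in reconstructions — it marks the FOV —
and metrics mask to the inscribed circle instead. Volumes are stacks of
independently reconstructed slices; sagittal reslicing is a pure axis
re-indexing (an involution, verified voxelwise).

# The artifact network

The network maps a corrupted FBP slice (scaled to [−1, 1] by the maximum
absolute intensity of the training inputs; the constant is stored with the
model) to its artifact image — reconstruction minus reference — and the
final reconstruction subtracts the prediction. Architecture: a U-Net
whose convolution blocks are zero-padded 3×3 convolution → ReLU → batch
normalization → squeeze-and-excitation gate (global average pool, two-layer
bottleneck of reduction ratio 16, sigmoid gates); 2×2 max-pooling down;
bilinear ×2 upsampling followed by a zero-padded 2×2 convolution up (the
transposed-convolution alternative is provided and is the regression
baseline for the checkerboard test); skip concatenations; a linear 1×1
output head with no softmax. Zero padding keeps every feature map at the
input size, so output size equals input size at any depth. Defaults follow
the original U-Net convention — depth 4, 64 base channels doubling per
level — and are fully configurable.

There is no deep-learning framework in the package's dependency set; the
forward pass, backpropagation and Adam are implemented in the package
(im2col/GEMM convolutions in compiled code, gradients verified against
finite differences in the test suite). Training minimizes the mean squared
error of the predicted artifact plus an ℓ₂ penalty (10⁻⁴) on convolution
kernels; the learning rate is 10⁻³ for the first 100 epochs, then decays
geometrically to 10⁻⁵ at the final epoch ("gradually decreases" realized
as log-linear decay; batch size 4 by default; a 5 % holdout drives a
validation-loss log and can be disabled). Batch normalization uses
accumulated running statistics at inference, so a trained network is a
pure function.

# Training corpus

`build_corpus()` reproduces the data recipe: 10 phantoms × 20 uniformly
selected slices (over the central 80 % of the grid, avoiding empty top and
bottom slabs) + 400 surrogate images = 600 base images, expanded by
90/180/270° rotations (exact pixel permutations) to 2400. Each image is
projected over −50°…50° at 1°, corrupted at a photon level drawn uniformly
from {10⁴, 5×10⁴, 10⁵}, and reconstructed at half resolution — directly
for the 1200 originals + 90° rotations, after two PWLS sweeps for the 1200
other rotations. The reference for the artifact target is the block-mean
of the clean image on the reconstruction grid. The manifest (source,
rotation, photon level, PWLS flag, seeds) makes every pair reproducible.

# The desk-scale experiment

The full-scale training run (500 epochs on 2400 pairs at 256²) is a
GPU-class computation; the package's end-to-end check runs a scaled-down
version chosen to preserve the *regimes* that the method's qualitative
result depends on: 200 pairs at 64² (3 phantoms × 14 slices + 8 surrogate
images, ×4 rotations — weighted toward phantom content since the held-out
evaluation is a phantom), a depth-2 network with 10 base channels, 50
epochs at batch 8 with a 5 % validation holdout. Shrinking the grid by 8× shortens attenuation paths by the
same factor, which would make photon noise negligible and void the
comparison of PWLS variants; the desk corpus therefore scales the photon
levels to {1750, 8750, 17500} — chosen so a typical through-cell ray keeps
the transmission counts of the full-scale setup (`N0 e^{-p}` matched for
`p ≈ 2` shrinking to `p/8`) — and evaluates at the noisiest level. On a
held-out phantom the experiment asserts the method's ordering — U-Net
variants beat their FBP inputs on RMSE-in-FOV and SSIM, and PWLS
preprocessing helps both — rather than absolute values.

# Metrics

RMSE is computed inside the inscribed FOV circle (radius `out_size/2`;
the truncation ring sits at its boundary). SSIM uses the standard
constants `K1 = 0.01`, `K2 = 0.03`, an 11-tap Gaussian window (σ = 1.5),
valid-mode windows only, and the reference slice's data range; a
brute-force windowed evaluation of the formula serves as its oracle in the
tests. Volume evaluation compares each reconstructed slice with the
analytic phantom slice; pure-background slices have no data range and are
excluded from SSIM means.

# Numerical choices and degenerate inputs

* Grids are centre-symmetric: index `i` maps to coordinate `i − (n+1)/2`;
  the same convention is used by the projectors, the backprojector and the
  slice renderer, so no half-pixel registration error accumulates.
* Poisson corruption clamps zero counts to one photon before the log.
* `n_iterations = 0` or `β = 0` make the PWLS denoiser the identity;
  constant inputs are exact fixed points.
* Degenerate inputs fail loudly: zero ellipse semi-axes, negative line
  integrals, all-zero normalization sets, constant SSIM references,
  even-length Ram–Lak kernels, non-square rotation inputs.
* Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state; derived sub-seeds stay below 2³¹.

# Known limitations

* The measured Table-1-style FBP figure is sensitive to phantom geometry
  that no published value pins down (ellipsoid sizes, slab extent). With
  this package's generator the mean RMSE-in-FOV of plain FBP at
  `N0 = 10⁴` over a full 512³ phantom comes out at ≈3.3×10⁻³ µm⁻¹,
  roughly 30 % above the reference value the pipeline is modelled on; the
  decomposition (truncation cupping ≈ noise > missing-wedge increment)
  suggests the difference lies in the unknown slab/cell geometry rather
  than in the operators, each of which is validated independently.
* PWLS at the corpus stage operates on 1D detector rows (single-slice
  sinograms); full projection stacks get the 2D 4-neighbourhood.
* The discrete projector deviates from the analytic sinogram near rays
  tangent to discontinuous edges (rasterization, see above).
* The U-Net implementation is CPU-bound R/RcppArmadillo: fine for the
  desk-scale experiment and for applying a trained model slice-wise, not
  for full-scale 500-epoch training.
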