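---
title: "Contour propagation with progressively trained registration networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour propagation with progressively trained registration networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propnet)
```

## The problem

In MR-guided prostate radiotherapy a clinical target volume (CTV) is
delineated once on a pretreatment scan. Before each of the ~20 daily
treatment fractions a fresh MR scan is acquired, and the CTV contour must be
transferred onto it within the time the patient is on the table. Classical
deformable registration solves an optimization problem per image pair and
takes minutes; `propnet` instead trains a convolutional network that maps a
(pretreatment, fraction) image pair directly to a dense deformation vector
field (DVF) in a single forward pass, and warps the pretreatment CTV mask
through a spatial transformer layer (STL).

Writing $I_M$ for the moving (pretreatment) image, $I_F$ for the fixed
(fraction) image, $C_M$ for the pretreatment mask and $u$ for the predicted
displacement (in voxels, on the fixed grid), the propagated contour is the
pull-warp

$$\hat C_F(x) = C_M\bigl(x + u(x)\bigr),$$

with nearest-neighbor sampling at inference so the output stays binary.

## Supervision on synthetic deformations

No paired ground-truth deformations exist for real scans, so training pairs
are manufactured: starting from one image $I$ and mask $S$, a random
multi-scale B-spline transform $T_{learned}$ (lattices $2^3, 4^3, 8^3, 16^3$
with uniform coefficient amplitudes 6.4, 3.2, 1.6, 0.8 voxels) is the
quantity to recover, and a random rigid + coarse B-spline transform
$T_{augm}$ (rotations within 0.1 rad, translations within 12.8 voxels)
augments the anatomy. The network sees $I(T_{augm})$ and
$I(T_{augm} \circ T_{learned})$; both are produced by composing the
transforms on coordinates first, so each image is interpolated exactly once
(third-order B-spline with a recursive prefilter). The supervision target is
the dense field of $T_{learned}$.

Three supervision variants are preset. With $\hat T$ the predicted and $T$
the true transform,

$$L = k_{overlap} L_{overlap} + k_{dvf} L_{dvf},$$
$$L_{overlap} = 1 - \frac{2\sum_x C_F(x)\, C_M(\hat T(x))}{\sum_x C_F(x) + C_M(\hat T(x)) + \varepsilon}, \qquad
  L_{dvf} = \frac{1}{|\Omega_F|}\sum_x \lVert T(x) - \hat T(x)\rVert_2^2,$$

with presets overlap $(1,0)$, deformation $(0,1)$ and hybrid $(1,1)$, and
$\varepsilon = 10^{-5}$ guarding empty masks. Nearest-neighbor sampling has
zero gradient in the sample coordinates, so during training the STL samples
the mask trilinearly (soft values feed $L_{overlap}$); at inference it
switches to nearest neighbor. This is the one place where the training-time
and test-time operators differ, and it is the standard resolution of the
differentiability requirement.

## Architecture and progressive schedule

The network is a 3D U-net over `levels` resolution levels (default five,
$128^3$ down to $8^3$), two input channels (moving, fixed — in that order)
and three output channels $(u_x, u_y, u_z)$ in full-resolution voxel units.
Details the source publication leaves open are fixed as configuration
defaults: two $3^3$ convolutions + batch normalization + ReLU per level,
$2^3$ max pooling, trilinear decoder upsampling followed by a convolution,
feature counts 32 at the finest level doubling downward capped at 256. Every
level has an input head (average-pooled copy of the two-channel input, one
convolution, added at the level's summation node) and an output head (a
$1\times1\times1$ convolution to three channels, upsampled trilinearly to
full resolution). Output heads are zero-initialized so an untrained network
predicts the identity transform.

The final field is $u = \sum_\ell \alpha_\ell u_\ell$ where the
$\alpha_\ell$ follow the progressive schedule: the coarsest level alone for
$N$ iterations, then a linear $M$-iteration ramp to the next level, then
$2N$-iteration plateaus alternating with $M$-iteration ramps. With the
defaults $N = 1000$, $M = 2000$ and five levels the finest level reaches
weight one exactly at iteration 15000, the full training budget; the ramps
are continuous, weights always sum to one, and at most two adjacent levels
are active. Optimization is plain SGD with momentum 0.5, learning rate 0.01,
batch size one, one freshly drawn synthetic pair per iteration; inference
uses an exponential moving average (decay 0.99) of the batch-normalization
statistics.

Why these are hand-written: the network, its backpropagation and the STL are
implemented directly in R/Rcpp (chunked im2col + GEMM convolutions), and the
gradients of every layer and of both losses are verified against central
finite differences in the test suite (relative agreement ~1e-8 for
parameters, 1e-4 tolerance asserted).

## The pelvic phantom

Clinical scans are not distributed with this package, so a synthetic
"patient" stands in: a bright smooth-edged ellipsoidal CTV (semi-axes
25 x 20 x 18 mm) centered in a fixed 200 x 200 x 115 mm field of view —
the window the preprocessing produces from the clinical acquisition — plus a
bladder analog (bright, superior-anterior), a rectum analog (dark
posterior tube), band-limited Gaussian texture (correlation length 8 mm,
amplitude 0.15 of the intensity scale, comparable to tissue contrast in T2
turbo-spin-echo pelvic MR; deformations must be observable away from organ
boundaries, which is what real tissue texture provides), and additive noise
(sigma 0.02). The mask is the exact ellipsoid rasterization. Because the
field of view is fixed, the same anatomy is generated at any grid size;
transform amplitudes defined in voxels of the 128-voxel grid are scaled by
`grid/128` so smaller grids see geometrically identical deformations.

Inter-fraction variation warps the same anatomy by an independent small
rigid + coarse B-spline transform per fraction (rotations within 0.05 rad,
translations and B-spline amplitudes 2.5% of the grid, about 5 mm) — the
few-millimeter prostate motion reported for MR-Linac treatment courses. What
the phantom does not emulate: MR physics (coil profiles, Rician noise,
artifacts), bladder-filling biomechanics, and inter-patient anatomical
variability beyond the random texture. Tests passing on phantoms therefore
demonstrate the correctness of the pipeline and the learnability of the
synthetic task, not clinical accuracy.

## Preprocessing

Clinical volumes are cropped axially to the CTV plus a 30 mm margin, then
resampled to the network grid by center-cropping a factor 2 in-plane and
1.33 axially: a 400 mm field of view becomes 200 mm at 1.5625 mm voxels on a
128 grid. Images are interpolated with the prefiltered cubic B-spline, masks
with nearest neighbor; intensities are then min-max normalized to [0, 1].
The order crop → resample → normalize is a package decision (the source
leaves it open and it is configurable in the run config); normalizing last
means the network always sees the full [0, 1] range of the cropped window.
A constant crop normalizes to all zeros rather than erroring.

## Numerical choices

* Voxel (i, j, k), 0-based, has its center at `origin + (i,j,k) * spacing`;
  axes are (x, y, z) = (left-right, posterior-anterior, superior-inferior).
* Rasterization uses the even-odd rule with the half-open scanline
  tie-break; centers exactly on a lower edge are inside.
* B-spline lattices of size $n$ span the full extent with knot spacing
  $(D-1)/(n-1)$; coefficients are edge-replicated beyond the lattice. Since
  the cubic basis is a nonnegative partition of unity, displacements are
  bounded by the largest coefficient, which gives the 12-voxel bound for the
  composed learned transform by the triangle inequality.
* Pull-warping out-of-grid samples take fill value 0 (background after
  normalization); `compose_fields` extends the outer field constantly beyond
  its grid so translation composition is exact.
* Jacobians use central differences inside, one-sided at faces; folding
  counts strictly negative determinants.
* Nearest-neighbor rounding is `floor(x + 0.5)` (ties up), deterministic.
* HD95 pools both directed surface-distance sets (6-connectivity boundaries,
  exact distances in mm) and takes the type-7 quantile;
  `method = "max_directed"` gives the max-of-directed variant.
* The supervision noise floor: warping the moving mask by the target field
  reproduces the target mask only up to the double nearest-neighbor
  discretization (the moving mask is itself a rounded warp). Measured on the
  default phantom this gives a mean Dice of about 0.97 at $128^3$ and 0.94
  at $64^3$ — the accuracy ceiling any perfectly trained network can reach
  on binarized masks at these resolutions. The acceptance suite computes
  this number at $64^3$ with 100 samples (grid chosen to keep the check
  inside its runtime budget).

## Desk-scale experiments

The `desk` profile (`load_run_config(profile = "desk")`) shrinks everything
so the full pipeline runs on one CPU in minutes: $32^3$ grid, 3 levels, 8
base features, 500 iterations. Its schedule uses $N = M = 50$, ending the
progression at iteration 250 and leaving 250 iterations of ordinary
full-resolution training: a proportional scaling of the full schedule would
spend the entire budget before the finest head — the only head used at
inference — had received more than a ramp of gradients. The
cross-validation harness, the axial-shift experiment (−5 to +5 mm in 1 mm
steps, implemented by displacing the pretreatment resampling window before
preprocessing) and the CSV/JSON reporting all run at this scale in the test
suite.

Honest statement of what desk-scale training achieves: with the prescribed
optimizer (SGD, learning rate 0.01, momentum 0.5, batch size one) the
network's training loss decreases reliably within 500 iterations, but
learning a generalizable correspondence operator takes far longer — the
original training budget is 15000 iterations — and at 500 iterations the
predicted fields remain small (a few tenths of a voxel). Consequences for
held-out contour propagation at desk scale are reported by
`scripts/acceptance.R` rather than asserted here; the vignette makes no
claim the code does not compute.

## Limitations

* No diffeomorphic or inverse-consistent parameterization; folding is
  measured, not prevented.
* Single-structure propagation (one binary mask); multi-class propagation is
  out of scope.
* The phantom's realism limits, listed above; no claim of clinical-level
  accuracy is made or tested.
* DICOM / RT-STRUCT input is out of scope; volumes enter as NIfTI or
  MetaImage, contours as JSON polygon stacks.
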