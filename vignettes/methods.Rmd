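---
title: "Methods: automated vascular image-to-mesh construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated vascular image-to-mesh construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vesselmesh builds simulation-ready vascular surface models from 3D
angiographic volumes in two stages: a multiscale Bayesian segmentation
network turns intensities into voxelwise lumen probabilities, and an
unsupervised diffeomorphic deformation aligns an extracted surface with
the image gradients. This vignette documents the models, their
assumptions, every tunable that matters, and the numerical choices made
where the design was genuinely open.

## Synthetic phantoms as the test bed

Real angiographic datasets are large, access-restricted, and annotated
at variable quality, so all quantitative claims in this package are made
on synthetic branched-tube phantoms with exact ground truth
(`make_phantom()`). A phantom is a set of centerline curves with radius
profiles; the binary label is the exact tube indicator (distance to the
nearest centerline point below the local radius), the image is the
two-level intensity field (defaults: lumen 300, background 50, inside
the 0–500 CT clip window) blurred by a 1-voxel Gaussian and corrupted by
additive Gaussian noise (default SD 15), and the ground-truth surface is
the isosurface of the noise-free signed tube field with the designated
inlet/outlet caps cut open. The default layout
(`default_phantom_spec()`) is a curved main vessel of radius 10 voxels
in a 64³ grid with three branches of radius 3.5–5 voxels taking off at
distinct azimuths — loosely an aortic arch with supra-aortic branches.

What the phantoms emulate: the lumen-over-background contrast of
contrast-enhanced CT, partial-volume blur, additive noise, branched
topology, and open inlets/outlets. What they do not emulate: beam
hardening and streak artifacts, intensity inhomogeneity across the
field, pathological wall geometry, and neighboring bright structures
(bone, other vessels). Passing the phantom suite therefore demonstrates
the machinery is correct and self-consistent at realistic geometry and
noise levels — not clinical-grade accuracy on hospital data.

The deformation experiments use a longer-vessel variant (72³ grid, main
radius 7 voxels, one branch). The inlet/outlet gate freezes a zone of
roughly one cap radius plus its buffer around every opening; on the
default stubby phantom those zones cover most of the wall, leaving too
little mobile surface for a meaningful recovery measurement, while the
longer vessel leaves ~60% of the wall fully mobile — closer to the
length-to-radius ratio of a real aorta.

## Segmentation: a multiscale LoG network with Bayesian kernels

The segmenter combines three parts.

**LoG stream.** A bank of Laplacian-of-Gaussian kernels
\((x^2+y^2+z^2-2\sigma^2)/\sigma^4\,e^{-(x^2+y^2+z^2)/2\sigma^2}\)
evaluated at integer offsets, sizes 3/5/7/9/11 paired with
\(\sigma\) = 0.5/1.0/1.5/2.0/2.5 voxels. A filter of scale \(\sigma\)
responds maximally to tubes of radius about \(\sqrt2\sigma\), so the
bank spans small branches up to the main aorta. As printed, the filter
formula omits the Gaussian normalizing constant; we therefore
mean-subtract (so constant inputs give exactly zero response) and
L1-normalize each kernel so response magnitudes are comparable across
scales. Responses pass through a sigmoid to \([0,1]\).

**Bayesian kernels.** Each LoG kernel weight carries a mean-field
Gaussian posterior, initialized at the precomputed LoG values with
log-SD \(\log 0.02\), against priors N(0, \(\sigma_p^2\)) with
\(\sigma_p\) = 0.5/1.0/1.5/2.0/2.5 per level. Training maximizes the
ELBO — a voxel-averaged Bernoulli log-likelihood under reparameterized
weight samples minus a scaled KL term — jointly with a soft-Dice loss:
the minimized objective is `(1 - Dice) - ELBO`. The KL scale defaults
to 1/(patches per run) so the prior's pull is dataset-size aware.
Restricting the Bayesian treatment to the LoG stream keeps posterior
sampling cheap while placing the uncertainty where it matters: on the
scale-selective edge detectors whose ambiguity reflects image quality.

**Regular stream and fusion.** A small 3D U-Net (two 3×3×3
convolution+ReLU blocks per level reduced to one convolution per level
here, 2×2×2 max pooling, nearest-neighbor upsampling with skip
concatenation) extracts context features; its output is concatenated
with the LoG features and fused by three parallel dilated 3×3×3
convolutions (rates 1/2/4), summed, and mapped through a 1×1×1
convolution and sigmoid. All forward and backward passes are
hand-derived reverse mode over im2col+GEMM convolution kernels; every
analytic gradient is finite-difference checked in the test suite.

**Balanced gate.** Random patches are classified by the voxel
percentage \(V_p\) — the fraction of LoG-feature voxels strictly above
\(\tau = 0.5\) — against the threshold \(\beta = 15\%\) (at or above:
"main"; ties are main so the rule is deterministic). Two pools
(capacity 10) fill with classified patches; each training batch draws
an equal number (5) per class, making batches exactly class-balanced at
any stream prevalence. The gate statistic is informative because
training images are background-suppressed: outside-vessel voxels are
exactly zero, so only genuine vessel edges produce strictly positive
LoG responses. Classification uses the fixed precomputed LoG bank (the
stream's initialization) rather than the evolving Bayesian kernels:
the gate statistic then stays stationary over training, whereas
classifying with shrinking posterior means lets the voxel percentage
drift below β for every patch and starves one pool. Pool capacity and
draw shrink (2 and 1) in the test-scale configuration.

**Scales.** The reference-scale configuration (5 levels, 16 base
channels, depth 3+, 64³ patches, learning rate 1e-5, batch 8) mirrors a
GPU-scale setup and is not exercised in tests. The test-scale
configuration — 2 LoG levels (sizes 3 and 7, \(\sigma\) 1.0 and 2.5), 8
base channels, depth 2, 32³ patches, 200 Adam steps at learning rate
2e-3 on 6 phantoms — trains in minutes on one CPU and reaches held-out
Dice above 0.85. The learning rate is larger than the reference value
because 200 steps must traverse the same loss landscape that 5000
epochs would at reference scale.

**Inference and uncertainty.** Full volumes are segmented by
overlapping-patch tiling (default 16-voxel overlap, unweighted mean in
overlaps) at the posterior mean. Ensembles are generated by
re-segmenting under fresh posterior weight draws; the voxelwise SD map
concentrates at the lumen boundary, where kernel perturbations shift
the detected edge.

## Surface initialization

The probability volume is triangulated at level 0.5 by tetrahedral
decomposition of each grid cube into six tetrahedra around a fixed main
diagonal (a marching-cubes-family isosurfacer chosen because its case
analysis is derivable from first principles; binary labels are
pre-blurred by 1 voxel to reduce staircase bias). Vertices are
deduplicated by grid edge, orientation is outward by construction, and
the result is watertight away from the grid boundary.

Remeshing approximates a centroidal Voronoi resampling: vertices are
k-means clustered and the output mesh takes one vertex per cluster
centroid and one face per input triangle spanning three distinct
clusters. Clustering runs in position ⊕ scaled-normal space
(normal term weighted by twice the mean edge length) so the opposite
walls of thin tubes, Euclidean-close but antiparallel in normal, never
merge into one cluster. Degenerate clusterings are retried under a new
seed; inputs should be watertight. Smoothing then descends the weighted
sum of three regularizers — normal alignment across interior edges,
edge-length uniformity, and the umbrella (Laplacian) term, boundary
vertices excluded from the latter — with a fixed step (0.1), halving on
any step that increases the objective or flips a face normal. Weights
default to 1.0/0.1/0.5; all values were fixed on phantoms.

## Diffeomorphic surface alignment

The deformation model is a control-point LDDMM flow: \(N_s\) control
points (default 300) chosen by farthest-point sampling carry momenta
\(\xi_i\); the velocity field is Gaussian-kernel interpolation
\(v(x) = \sum_i K(x, s_i)\,\xi_i\) with \(K(x,y) =
\exp(-\|x-y\|^2/\sigma_K^2)\) (the exponent is used exactly as the
source formula prints it, without a factor 2), and control points and
momenta evolve under Hamiltonian dynamics, integrated together with all
mesh vertices by midpoint Runge–Kutta over \(T=1\) in 15 steps. The
kinetic energy drifts by well under 1% over the default discretization,
and flows in the tested momentum regime produce no face inversions —
the discrete signature of a diffeomorphism. \(\sigma_K\) defaults to
twice the mean nearest-neighbor spacing of the control points.

**Momentum prediction.** Initial momenta come from a graph network on
the mesh: two blocks of two Chebyshev spectral convolutions (order 3,
hidden width 64) with residual connections, acting on
centered/RMS-normalized vertex coordinates through the scaled
normalized graph Laplacian. The read-out layer is zero-initialized so
the first iterate is exactly the identity flow. Momenta are predicted
per vertex and read off at control-point vertices.

**Scaling gate.** Each boundary loop (inlet/outlet) defines a cap: its
center is the loop centroid and its radius the mean center-to-loop
distance (mean rather than max for robustness to the jagged rims of
voxel-derived meshes). The mobility field is 0 within the cap radius,
\(1-\exp(-(d-r)^2/2\sigma_g^2)\) in the buffer, and 1 beyond
\(r+3\sigma_g\), with Euclidean distances to the cap center; the
spec-stated half-radius buffer was reduced to a quarter radius because
phantom vessels are short relative to their caliber and the wider
buffer left no mobile wall. The field multiplies both the control-point
momenta and the carried vertex velocities: gating velocities (not just
momenta) keeps cap vertices displaced exactly zero — kernel
interpolation alone would always leak an exponentially small motion —
while leaving the Hamiltonian \((s,\xi)\) dynamics intact.

**Objective and optimization.** The per-case unsupervised loss is
\[-w_1 \log \sum_i G(\hat s_i) + w_2 L_{normal} + w_3 L_{edge} +
w_4 L_{laplacian},\]
with \(G\) the spacing-aware gradient-magnitude volume (central
differences, 1-voxel presmoothing) sampled trilinearly at deformed
vertices, and weights 1.0/0.2/0.01/0.1. The stabilizer inside the log
is 1e-8. Gradients with respect to vertex positions are fully analytic
(including the normal-loss term through the face-normal Jacobians, all
finite-difference verified). The pullback to momenta uses the
first-order sensitivity of the flow endpoint,
\(\partial x_v / \partial \xi_i \approx T\,\alpha_v\,
K(x_v^0, s_i^0)\,\alpha_i\) — the standard kernel (Sobolev) gradient
with the trajectory frozen at \(t=0\). For the small deformations this
module targets (a few voxels against \(\sigma_K\) of several
millimeters) the approximation is near-exact, and since the best
iterate by total loss is returned, only a descent direction is
required. The predictor is trained per case by Adam (default 2e-3, 300
epochs); gradients through the Chebyshev layers are exact.

The `direct` method — Adam on raw per-vertex displacements with the
same loss — is the ablation baseline: it reaches lower misalignment
energy (each vertex is free to chase its own gradient peak) at the cost
of a rougher surface (higher normal loss), which is precisely the
regularizing value of the flow parameterization.

## Metrics and uncertainty propagation

Dice uses \(2\sum g o / (\sum g^2 + \sum o^2)\), with two empty masks
defined to agree (Dice 1). ASD and Hausdorff operate on mesh vertices
as the surface point clouds (stated in the report metadata; no
point-to-triangle distances). The SNR at a point is mean over
population-SD (1/n) of the 10³-voxel window centered there, clipped
with a warning at grid borders. Ensemble surface uncertainty uses
nearest-point correspondence from the mean surface to each member; the
per-point SD of those distances is regressed (log scale) against local
SNR — on phantoms with spatially graded noise the slope is negative,
echoing at sign level the uncertainty–image-quality relation reported
at full scale.

## Degenerate inputs and numerical edges

Out-of-bounds trilinear samples clamp to the border value and report a
clamped fraction. Gradient stencils fall back to one-sided differences
at grid faces. Empty meshes, non-manifold edges, faces repeating a
vertex, and 2D volumes are rejected at construction. The voxelizer
classifies the exact-90° angle as outside, making the inside rule
deterministic. Probability clamping at 1e-7 guards the Bernoulli
log-likelihood. Training aborts on a non-finite objective; the flow
integrator aborts on non-finite states; smoothing and deformation both
retreat (step halving, best-iterate tracking) rather than diverge.

## Problem sizes used by the test suite

Unit tests run on 8³–64³ volumes and meshes of 400–2500 vertices. The
scaled-down training experiment uses the 2-level/8-channel/32³
configuration for 200 steps (one patch per class per step) on six
phantoms; the deformation recovery experiment perturbs a 72³
longer-vessel phantom surface (remeshed to 2000 vertices) by a smooth
2-voxel field and optimizes for 300 epochs; uncertainty propagation
uses small ensembles with shortened (60-epoch) deformations. These
sizes were chosen so the full suite completes on a single CPU while
leaving each experiment in the regime where its acceptance property is
stable.

## Known limitations

The segmenter's test-scale architecture is far smaller than a clinical
model and is validated only on phantoms. The cluster-dual remesher
requires features a few voxels across; tubes under ~2 voxel radius can
defeat it (it fails loudly rather than returning a broken mesh). The
endpoint-sensitivity gradient is first-order in the momenta; very large
deformations (displacement beyond ~2\(\sigma_K\)) would need exact
adjoint integration. Cap detection assumes each opening is a single
clean boundary loop. Axis-aligned grids only; DICOM series and oblique
direction matrices are out of scope.
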