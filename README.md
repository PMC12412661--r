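# vesselmesh

Automated construction of patient-specific vascular surface models from
3D angiographic volumes, with uncertainty quantification. The package is
aimed at researchers building simulation-ready (CFD/FSI) vessel
geometries who want a reproducible, fully scripted alternative to manual
segmentation-and-lofting workflows — and at method developers who need a
controlled synthetic test bed for every stage of such a pipeline.

## What it does

The pipeline runs image → voxels → surface → refined surface:

1. **Segmentation.** A multiscale network combines a bank of 3D
   Laplacian-of-Gaussian filters,
   `(x²+y²+z²−2σ²)/σ⁴ · exp(−(x²+y²+z²)/2σ²)`, at sizes 3/5/7/9/11
   (σ = 0.5…2.5 voxels) with a small 3D U-Net and a dilated-convolution
   fusion block. The LoG kernel weights are Bayesian (mean-field
   Gaussian posteriors, priors N(0, σ²ₚ) with σₚ = 0.5…2.5 per level);
   training minimizes `(1 − Dice) − ELBO` over patches assembled by a
   *balanced gate* that classifies each patch by its voxel percentage
   `Vp = #{oᵢ > 0.5}/N` against β = 15% and draws exactly equal numbers
   of main-vessel and branch patches.
2. **Surface initialization.** Isosurface extraction on the probability
   volume (tetrahedral-decomposition marching), approximate
   centroidal-Voronoi remeshing, and smoothing by gradient descent on
   normal/edge/Laplacian regularizers.
3. **Diffeomorphic refinement.** A control-point LDDMM flow — velocity
   `v(x) = Σᵢ K(x, sᵢ) ξᵢ` with `K(x,y) = exp(−‖x−y‖²/σ²)`, Hamiltonian
   dynamics integrated by midpoint RK2 over T = 1 in 15 steps — deforms
   the surface to minimize the unsupervised loss
   `−w₁ log Σᵢ G(ŝᵢ) + w₂ L_normal + w₃ L_edge + w₄ L_laplacian`
   (weights 1.0/0.2/0.01/0.1), where `G` is the image
   gradient-magnitude volume. Initial momenta are predicted by a
   Chebyshev graph-convolution network on the mesh; an inlet/outlet
   *scaling gate* freezes cap regions so open ends cannot retract.
4. **Metrics and UQ.** Dice, average surface distance, Hausdorff
   distance, local SNR, and posterior-sampling ensembles whose
   per-point SD maps quantify segmentation and surface uncertainty.

Everything is testable without clinical data: a phantom generator
produces branched vessels with exact ground-truth labels and surfaces
under controllable blur and noise.

## Worked example

```r
library(vesselmesh)

spec <- default_phantom_spec(seed = 1)   # branched aortic-arch-like tube
ph <- make_phantom(spec)
print(ph$image)
#> <scalar_volume> 64x64x64 voxels, spacing (1, 1, 1) mm, origin (0, 0, 0) mm,
#>   range [-23.23, 354.8]
print(ph$mesh)
#> <triangle_mesh> 8854 vertices, 17185 faces, 5 boundary loop(s)

# label -> surface -> uniform remesh -> smooth, then compare to truth
surf <- extract_isosurface(ph$label)
surf <- remesh_uniform(surf, 2000, seed = 1)
surf <- smooth_mesh(surf, smoothing_weights(iterations = 20))
open_surf <- cut_phantom_caps(surf, spec)
cat(sprintf("ASD to ground truth: %.3f mm\n", asd(open_surf, ph$mesh)))
#> ASD to ground truth: 0.520 mm
cat(sprintf("Hausdorff:           %.3f mm\n", hausdorff(open_surf, ph$mesh)))
#> Hausdorff:           1.411 mm

# hole-filling voxelization round trip, split by region
rep <- metrics_report(voxelize_surface(extract_isosurface(ph$label),
                                       ph$image),
                      ph$label, region = ph$region)
print(rep)
#> <metrics_report> Dice 0.9968 | main 0.9994 / branch 0.9687
```

The numbers read as: the reconstructed surface sits half a voxel from
the true lumen wall on average (worst point 1.4 mm), and converting the
surface back to voxels reproduces the ground-truth label almost
perfectly, slightly worse in the thin branches where discretization
bites hardest.

Training a segmenter and running the full pipeline end to end:

```r
train <- lapply(1:6, function(s)
  make_phantom(default_phantom_spec(seed = s))[c("image", "label")])
fit <- train_segmenter(train, seg_config(patch_size = 32L,
                                         base_channels = 8L, depth = 2L,
                                         log_sizes = c(3L, 7L),
                                         log_sigmas = c(1, 2.5),
                                         prior_sds = c(1, 2.5),
                                         epochs = 200L,
                                         learning_rate = 2e-3))
res <- run_pipeline(pipeline_config(model = fit$model, seed = 7))
res$metrics
```

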