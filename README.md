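# spinefit

CT-free 3D planning of transpedicular needle trajectories from two
calibrated 2D radiographs, in R.

Vertebroplasty — injecting bone cement into a fractured vertebral body
through a needle passed along the pedicle — is usually planned on a
preoperative CT that, for these patients, often does not exist. `spinefit`
implements the alternative: reconstruct the patient's vertebra in 3D from
just two intraoperative X-ray-like views with known pinhole geometry, and
read the needle corridors off the reconstruction.

The package is aimed at researchers in image-guided intervention and
statistical shape analysis who want a fully inspectable, dependency-light
reference implementation of this pipeline, runnable end to end on
synthetic data without any external dataset.

## The method

1. **Statistical shape model (SSM).** Corresponded vertebral surfaces
   (Generalized Procrustes alignment; ICP + coherent point drift for
   meshes of arbitrary topology; iterative ICP/PCA refinement) yield a
   point-distribution model. An instance is
   `x_i = R (s (x̄_i + W_i (c ⊙ √λ))) + t` — rotation `R`, translation
   `t`, and standardized shape coefficients `c` along the PCA modes `W`
   (15 retained by default), bounded at ±3 SD.
2. **Differentiable splat rendering.** Instance vertices are projected
   through each pinhole camera `P = K[R_cam | t_cam]` and rendered as
   additively accumulated 2D Gaussians (image-plane width `σ_w·f/z`). The
   kernel is truncated with a C¹ roll-off, so the map from the 21
   parameters (3 rotation + 3 translation + shape coefficients) to the
   images is differentiable; gradients are analytic and validated against
   finite differences.
3. **Registration.** Pose is initialized by triangulating landmarks
   detected in both views (≥3 in common; silhouette-derived backup
   landmarks below that) and solving a least-squares similarity
   transform. A staged adaptive-momentum optimizer then minimizes the
   multi-view normalized-cross-correlation loss `mean(1 − NCC)` over pose,
   shape, and a nuisance kernel width.
4. **Path planning.** Entry/exit points annotated once on the template
   (barycentric face anchors) propagate to the fitted vertebra with no
   per-case optimization. A plan breaches if the pedicle wall comes
   within 2.5 mm of the trajectory axis (exact contact detection for the
   5 mm-diameter cylinder); bipedicular success requires both sides
   breach-free. A 2D-plan-then-triangulate baseline is included for
   comparison, as are DICE / normalized surface Dice / HD-95 / MASD
   evaluation metrics.

A `synthetic_anatomy` layer generates watertight parametric vertebra
phantoms with exact landmarks and known pedicle axes, renders noisy target
views with a deliberately mismatched kernel (inverse-crime mitigation), and
simulates landmark detections — so every stage is testable from a clean
checkout.

## Worked example

```r
library(spinefit)

# build a shape model from a synthetic phantom population
pop   <- sample_population(20, seed = 1)
model <- build_ssm_population(pop, k = 8)
model
#> vertebra_ssm: 1052 vertices, 8 modes (from 20 training shapes)
#>   variance in retained modes: 99.8%
#>   template path annotations: left/right

# a held-out "patient", two calibrated views, noisy detections
patient <- sample_population(1, seed = 99)[[1]]
cams    <- biplanar_cameras(colMeans(patient$vertices))
targets <- make_target_views(patient, cams, seed = 99)
dets    <- lapply(seq_along(cams), function(v)
  simulate_detections(patient, cams[[v]], pixel_noise_sd = 1,
                      dropout_prob = 0.1, seed = 99 + v,
                      view_id = names(cams)[v]))

fit <- reconstruct(model, targets, cams,
                   init = initialize_pose(dets, cams, model))
fit
#> vertebra_fit: ncc loss 0.01849 -> 0.00498 over 248 evaluations
#>   init: 8 landmarks, views 90.0 deg apart

voxel_dice(fitted(fit), patient, spacing = 1)
#> [1] 0.9940012

for (side in c("left", "right"))
  print(breach_check(propagate_path(model, fit$params, side = side), patient))
#> path_plan (left): 5.0 mm cylinder, length 33.7 mm, wall distance 4.80 mm [ok]
#> path_plan (right): 5.0 mm cylinder, length 34.0 mm, wall distance 4.76 mm [ok]
```

The fit object supports `print`, `summary`, `coef` (the fitted 21
parameters), `fitted` (the reconstructed mesh), `residuals` (per-view
image residuals) and `plot` (the loss trajectory). Shape models support
`print`, `summary` (per-mode variance table), `predict` (instantiation)
and `simulate` (random plausible shapes). Eight of the ten anatomical
landmarks survived dropout in both views here; the reconstruction recovers
the held-out phantom at DICE 0.994 and both propagated trajectories clear
the pedicle walls by ≈4.8 mm, well outside the 2.5 mm breach margin.

Batch experiments with per-case CSV/JSON reports:

```r
rep  <- run_demo(pipeline_config(n_test = 10, seed = 1), out_dir = "demo_out")
base <- run_baseline(pipeline_config(n_test = 10, seed = 1), out_dir = "base_out")
```

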