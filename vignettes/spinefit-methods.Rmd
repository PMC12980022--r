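---
title: "Vertebral shape models, differentiable splat registration and transpedicular planning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebral shape models, differentiable splat registration and transpedicular planning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Vertebroplasty delivers bone cement into a fractured vertebral body through
a needle passed along a transpedicular corridor. Planning that corridor in
3D normally requires a CT scan; in the common case where none exists, the
only intraoperative information is a pair of calibrated 2D radiographs from
arbitrary (not necessarily orthogonal) viewpoints. `spinefit` reconstructs a
patient-specific vertebral surface and its two transpedicular trajectories
from exactly that input: a statistical shape model supplies the anatomical
prior, a differentiable renderer links the model's 3D parameters to
simulated radiographs, and a gradient-based optimizer aligns rendered and
observed images.

# The shape model

The model is a classical point-distribution model over `N` corresponded
surface vertices. Training shapes are similarity-aligned by Generalized
Procrustes Analysis (centroid to the origin, centroid size to one, Kabsch
rotations onto an iterated consensus), rescaled to metric units at the
population-mean centroid size, and decomposed by PCA. A model instance is

$$ x_i = R\,\big(s\,(\bar{x}_i + W_i\,(c \odot \sqrt{\lambda}))\big) + t $$

with `R` a rotation (axis-angle, exponential map), `t` a translation in mm,
`c` the standardized shape coefficients, `W_i` the per-vertex rows of the
orthonormal mode basis and `λ` the mode variances. Fifteen modes are
retained by default; on the phantom populations shipped with the package
the available rank is usually smaller and `build_ssm()` reduces the count
with a warning. Coefficients are stored in units of mode standard
deviations and bounded at ±3, which gives the optimizer uniform scaling and
confines instances to plausible shapes. Because Procrustes alignment
removes scale, an isotropic scale `s` is estimated once at initialization
(from the landmark similarity fit) and frozen during gradient optimization;
the optimized degrees of freedom are exactly the 6 pose parameters plus the
shape coefficients.

For meshes that do not share the template's vertex count, correspondence is
established by rigid ICP (nearest neighbours, lowest index on ties, Kabsch
updates, monotone mean residual) followed by non-rigid coherent point
drift: a Gaussian-mixture registration whose motion-coherence prior is a
Gaussian kernel of width `beta = 2` with weight `lambda = 3` in
internally normalized units — the common defaults for this algorithm. The
regularized negative log-likelihood is tracked and is nonincreasing across
EM steps. Models are then refined by alternating (1) a fit of the current
model to every raw mesh, (2) correspondence updates from the fitted
instance, and (3) a PCA rebuild, stopping if the population residual ever
increases.

The per-mesh fit in step (1) is point-to-surface least squares with
Gauss-Newton: residuals to the closest point on the target surface for the
first half of the iterations (tolerant of tangential parametrization
slide, with Levenberg–Marquardt damping because slide directions are
nearly unobservable), then the same number of point-to-point steps against
nearest target vertices, which pin the parametrization once the surfaces
coincide. With five steps per stage this refits model-generated meshes to
machine precision, which is what makes refinement a fixed point on
in-subspace populations — a property the test suite asserts.

Annotation transfer uses the volumetric DICE between the fitted instance
and the raw mesh as a quality gate: at or above 0.85 the landmarks and
template path anchors are propagated, below it the case is rejected with
its score. The threshold is inclusive by documented choice.

# Rendering and registration

Each rendered view projects the instance vertices through a calibrated
pinhole camera `P = K [R_cam | t_cam]` with perspective divide, and
accumulates one 2D Gaussian per visible vertex. Accumulation is additive —
radiographs integrate attenuation along rays, so splat intensities add
rather than occlude — and the image is max-normalized. An isotropic
world-space kernel of width `σ_w` maps to an image-plane width
`σ_px = σ_w f / z` per splat; the default `σ_w` is the mean
nearest-neighbour spacing of the rendered point set, the smallest width
that still gives a connected silhouette. An anisotropic variant (2D
covariance `J Σ Jᵀ` with `Σ` aligned to the surface normal) is provided as
a forward-only interpretation, since the exact covariance construction for
these renderers is a design choice; the analytic gradient path supports
the isotropic renderer.

Kernels are truncated at 4σ with a C¹ roll-off,
`φ(s) = e^{-s} - e^{-s_c} + e^{-s_c}(s - s_c)` for `s = r²/2σ²`, so both
the image and its derivative are continuous as footprints slide across
pixel boundaries. This matters because all gradients are analytic: the
backward pass chains the similarity gradient `∂L/∂I` through the splat
kernel to per-splat `(∂L/∂u, ∂L/∂v, ∂L/∂σ)`, through the pinhole Jacobian
to camera and world coordinates, and through the exponential-map Jacobian
and the mode basis to the axis-angle, translation and coefficient
parameters. The contract — enforced by tests on seeded random instances —
is agreement with central finite differences (step 1e-3 per unit) to a
relative error below 1e-3, 1e-2 for rotation components; a hard truncation
would leave kernel-edge discontinuities of order `e^{-8}` that violate it.

The default similarity is normalized cross-correlation: the loss is the
mean over views of `1 − NCC`, in `[0, 2]`, invariant to affine intensity
maps, with a constant image contributing 1 under a warning. Learned
multi-view similarities fit the same `similarity_metric` plug-in contract
(a loss plus its image-space gradient) but no trainable implementation is
shipped. Because NCC is scale-invariant, the max-normalization of rendered
images does not affect the loss or its gradient.

Pose is initialized from 2D landmark detections: landmarks present in both
views are triangulated (midpoint of the common perpendicular between the
back-projected rays; the segment length is the residual, and rays within
1° of parallel raise a degenerate-geometry error), then a least-squares
similarity transform maps the template landmarks onto the triangulated
points. At least three common landmarks are required; below that, five
backup landmarks derived from the projected silhouette's bounding box
(centre and edge midpoints) are paired with the template's bounding-box
face centres. That pairing assumes roughly anteroposterior/lateral
geometry — the regime the fallback is intended for — and is therefore only
a coarse seed for the optimizer under strongly oblique views. Fewer than
three usable correspondences is an initialization failure and the case is
skipped with a categorized reason. A warning is issued when the views are
separated by less than 15°, where the triangulation geometry weakens.

Optimization is staged first-order descent with adaptive momentum
(Adam-style): stage 1 frees the pose for 150 iterations, stage 2 pose and
shape for 250, with per-block step sizes 0.01 rad, 0.5 mm and 0.05
standardized units, convergence declared when the loss moves less than
1e-6 over 20 iterations, coefficients clamped to ±3, and the best-seen
(not final) parameters returned. The raw NCC gradient varies over orders
of magnitude across parameters, so the per-block step sizes act as
per-parameter step scales under the adaptive normalization — with plain
momentum they would be meaningless. Alongside the 21 parameters the
optimizer self-calibrates the splat kernel width on a log scale (step
0.02). This nuisance parameter is what makes registration robust to the
unknown blur of the target images: target views are deliberately rendered
with a 1.5× wider kernel plus noise (see below), and without width
self-calibration the silhouette dilation that mismatch causes is absorbed
by the shape coefficients as a systematic inflation bias.

# Path planning

Entry and exit points are annotated once on the template as barycentric
anchors on template faces — sub-facet precision, and exact equivariance of
the propagated path under rigid motion, which the tests assert bit-level.
For the phantom template the annotation is derived automatically: the
entry anchors at the posterior pedicle-axis endpoint, the exit where the
extended axis pierces the anterior surface (Möller–Trumbore ray casting).
Propagation to a reconstruction is barycentric evaluation on the
instantiated mesh; no per-case optimization.

A plan is screened by sampling the labelled pedicle wall (at least 10
samples per mm², area-weighted and seeded) and taking the exact minimum
point-to-segment distance to the path axis. The trajectory breaches when
that distance falls below 2.5 mm — with the default 5 mm cylinder diameter
this detects cylinder–wall contact exactly, which is why the distance is
measured to the axis rather than the cylinder surface. A case-level
*bipedicular success* requires a breach-free plan on both sides.

The comparison baseline plans in 2D first: path endpoints detected
independently in each view are triangulated to 3D and a 5 mm cylinder is
constructed; a missing endpoint in any view fails that pedicle. This
baseline ignores the cross-view coupling through the underlying 3D path,
which is precisely the weakness the model-based route removes.

# The synthetic cohort

Phantom vertebrae are schematic unions of closed primitives: an elliptic
cylinder body (radii 18 × 14 mm, height 30 mm), two tube pedicles (radius
6 mm, length 14 mm, 15° inward inclination) whose centerlines are the
ground-truth trajectories, and capsule processes. The ten canonical
landmarks sit on exact mesh vertices, mesh connectivity is independent of
the parameters (so populations are corresponded by construction), and
every component is watertight and outward-oriented. Populations draw
log-normal multiplicative variation on lengths and radii (5–8%) and
additive normal variation (2°) on the pedicle inclinations — moderate
inter-subject variability at phantom scale, chosen once.

The phantoms are deliberately not anatomical. What they guarantee is
geometric ground truth: known axes, exact landmarks, labelled cortical
walls, watertightness. Consequently the green test suite demonstrates the
*mechanisms* — correspondence, rendering, gradients, recovery, planning
rules — not clinical accuracy on real vertebrae, which additionally
involves soft-tissue clutter, beam physics, detector response and
pathological shape variation that the cohort does not emulate. Two
details of the union-by-overlap construction are worth noting: interior
junction surfaces (e.g. the body wall where a pedicle tube passes through
it) remain part of the mesh, and the flat tube end caps are crossed by the
path by design, so the caps are labelled as junction rather than cortical
wall and the breach rule measures only the lateral pedicle surface.
Because the 16-gon tube wall lies at `r·cos(π/16)`, the parameter guard
requires the pedicle radius to exceed 2.5/cos(π/16) mm so a centred 5 mm
path is breach-free by construction.

Target radiographs are rendered with a kernel 1.5× wider than the
registration default, then corrupted with multiplicative log-normal
speckle (σ = 0.05) and additive Gaussian read noise (σ = 0.01) — an
inverse-crime mitigation, so the registration never compares an image
against a bitwise copy of its own renderer's output. Detections add
isotropic Gaussian pixel noise (default 1 px) and independent dropout
(default 0.1); confidence is one minus the dropout draw.

# Numerical choices

* Voxelization decides voxel-centre containment by signed ray crossings
  along +z, which treats overlapping closed components as their union. The
  grid is staggered half a voxel off the mesh bounds plus a tiny
  anisotropic jitter so sample points never land exactly on faces or
  shared edges; both offsets track the mesh bounds, keeping the operation
  translation-covariant. Default spacing 0.5 mm (1 mm in the batch
  pipeline, where DICE at phantom scale is insensitive to the refinement).
* Surface metrics (NSD with τ = 1 mm, HD-95, MASD) measure area-weighted
  seeded samples of one mesh by *exact* point-to-triangle distance against
  the other, in both directions — identical meshes score exactly
  zero/one, and doubling the sample count moves results by well under 1%.
  Plain point-set inputs fall back to point-to-point distances so small
  toy sets can be verified exhaustively.
* Ties in nearest-neighbour queries resolve to the lowest index;
  rotations near the origin use series expansions of the exponential map
  and its Jacobian.
* The whole pipeline is deterministic given its seeds: every sampler takes
  an explicit seed, the optimizer uses none, and batch reruns produce
  byte-identical reports.
* Reference problem sizes: phantoms of ~1050 vertices; 96×96 px views at
  focal length 500 px and 500 mm source distance (≈1 px/mm at the
  object); 800 rendered splats; populations of 20 with 8 modes for the
  batch experiments. These sizes put a full two-view reconstruction at a
  few seconds on one core while leaving the recovery experiment's error
  medians far inside their acceptance bands.

# Known limitations

* The learned similarity used by trained pipelines is represented only by
  its plug-in interface; NCC is the shipped metric, so capture range under
  heavy appearance mismatch is narrower than a learned loss could provide.
* The backup-landmark fallback presumes near-AP/LAT geometry; under
  arbitrary oblique pairs it seeds the optimizer coarsely.
* Anisotropic splats are forward-only; gradients cover the isotropic
  renderer.
* Phantom realism: no fracture morphologies, no imaging physics; region
  labels on fitted instances are template labels carried by
  correspondence.
* The multi-view interface accepts N views but the experiments and tests
  exercise the paired two-view setting.
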