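---
title: "Label-informed registration and volumetric morphometrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-informed registration and volumetric morphometrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(labelmorph)
```

## The problem

Registration-based (voxel- and tensor-based) morphometrics map every
subject image onto a common template so that dense shape information can be
compared statistically across groups. Intensity-driven registration works
well when subjects are broadly similar; it degrades or fails outright on
overt phenotypes — severe scoliosis, displaced or resized organs — because
the linear initialisation cannot approximate the gross shape difference and
the deformable stage then optimises from a bad starting point.
`labelmorph` implements an anatomy-aware alternative: anatomical label maps
(segmentations produced by any means) provide a priori regional
correspondences that initialise and optionally refine the registration,
alongside a conventional intensity-only arm for comparison, plus the
downstream morphometric machinery: log-Jacobian tensor-based morphometry
(TBM) with Benjamini–Hochberg FDR control, PCA of displacement fields
(morphospace), and physical label volumes with Welch t-tests.

## Data model and conventions

* **Grid**: images and fields live on an `image_grid` (shape, spacing in
  mm, origin, orthonormal direction matrix). Indices are 0-based and refer
  to voxel centers; `index_to_physical` is
  `origin + direction %*% (spacing * index)`.
* **Transforms** map *fixed-space* physical points into *moving-space*
  physical points. A composite `[A, F]` applies right-to-left:
  `x -> A(F(x))`. The **forward** composite of a registration maps
  template points into subject space; it is the map whose Jacobian TBM
  analyses and the one used to pull subject values onto the template grid
  (`warp_image` computes `out(x) = moving(T(x))`). The **inverse**
  composite feeds the deformation PCA.
* **Out-of-domain samples** return 0, the air/background value of a
  masked specimen image.
* **Displacement fields** store mm vectors per voxel and interpolate
  multilinearly; nearest-neighbour interpolation rounds half away from
  zero. Jacobians use central differences in physical coordinates with
  one-sided differences at the boundary and are reported as the natural
  log by default (`log J < 0` = local shrinkage); raw determinants are a
  flag away. Non-positive determinants become `-Inf` and are counted in a
  folding diagnostic rather than silently clipped.
* **Field inversion** uses a *damped* fixed-point iteration
  `v <- v + omega * (-u(x + v) - v)`. The classical undamped update
  (`omega = 1`) provably contracts only when the displacement gradient is
  below 1; we observed divergence on valid diffeomorphic fields with
  gradients around 0.5, so `omega` halves whenever the mean residual
  worsens. The routine reports its achieved residual and a convergence
  flag instead of failing.

## The registration pipeline

Both arms share the structure: (1) linear initialisation, (2) masked
deformable registration, (3) optional label-similarity refinement
(label-informed arm only).

**Stage 1, label-informed:** centers of mass of corresponding labels are
matched by weighted least squares — translation (1–2 shared labels), rigid
via orthogonal Procrustes with a proper rotation enforced, similarity
(one scale, Umeyama), or affine via weighted normal equations. Degenerate
geometry (collinear centroids, too few labels) falls back to the richest
well-posed model and flags the report. Weights default to 1 per label so
small organs anchor as strongly as large ones; voxel-count weighting is
available. The rotation center is the weighted mean of fixed centroids.

**Stage 1, intensity-only:** multi-resolution Nelder–Mead minimisation of
the masked mean-squared intensity difference over the chosen linear
model's parameters. Initialisation is the identity when a mask is given
(a center-of-mass guess computed from a moving image whose background
content is arbitrary can be badly biased — this broke the mask-respect
property in testing), otherwise the intensity centers-of-mass offset.

**Stage 2:** a greedy compositional demons-style engine stands in for a
full symmetric-normalisation optimiser while honouring the same contract.
Per iteration: a metric force (MSE demons force, or a local normalised
cross-correlation force with Gaussian window, default 4 voxels) is
computed on the fixed grid restricted to the mask, smoothed by
`update_sigma` (fluid-like, default 2 voxels), rescaled so the largest
step is `max_step` (default 0.4 voxels — below 0.5 each increment is
trivially invertible), composed into the running field, and the total
field smoothed by `total_sigma` (elastic-like, default 1 voxel). Steps
that increase the metric are rejected and the step size halved, so the
accepted-metric trace is non-increasing. Three resolution levels
(factor 2) with 60/40/20 iterations by default. The dense inverse is
obtained by fixed-point inversion of the accumulated forward field at the
end (rather than incrementally per iteration — same contract, less cost);
the forward/inverse composition residual inside the mask is tested at
0.1 voxel. MSE is the default metric: the target imagery is
single-modality microCT, and MSE is several-fold faster; LNCC is provided
for intensity-distorted data and is exercised in the tests.

**Stage 3 (optional):** each shared label is rendered as a real-valued
channel (Gaussian-smoothed indicator, sigma 2 voxels, or a signed-distance
surrogate) and the same engine minimises the weighted multi-channel MSE.
The exact functional form of the label similarity in the reference
ecosystem is not documented; the smoothed-indicator MSE is our documented
local choice. Refinement is off by default: it reduced endpoint error by
~10% on severe phantoms but tripled the label-arm cost.

**Template construction** iterates: register every subject to the current
template, average the warped intensities, and apply a mild unsharp mask
(sigma 1 voxel, amount 0.5) to counteract averaging blur; the initial
template is the plain voxelwise mean of the (rigidly pre-aligned)
subjects. Three iterations by default. No whole-cohort affine-average
(shape-update) correction step is applied — a deliberate simplification.

## Statistics

**TBM.** Per masked voxel, OLS of log J on intercept + group indicator;
the group-coefficient t with `nA + nB - 2` degrees of freedom is
numerically the pooled two-sample t (asserted at 1e-10 in the tests, and
pooled rather than Welch because the published analysis is a linear
regression with a genotype indicator). Voxels with non-finite log J are
excluded and counted; zero-residual-variance voxels get p = 0/1 by mean
equality and are flagged. FDR is Benjamini–Hochberg step-up, applied
within the analysis mask (mask-restricted was an open choice; the
alternative — whole-grid — only dilutes the ranking with air voxels). The
heatmap shows the group-mean difference of log J (the published figures do
not define their group summary; the mean difference is ours, documented)
over the significant set, clipped to [-1, 1].

**PCA.** Each subject's combined inverse field, sampled on the template
grid inside the body mask (mask-restricted, an open choice), contributes
one row of `d * n_masked` features; no per-channel variance normalisation
(raw mm displacements). Scores/components come from the SVD of the
centered matrix via the n-by-n Gram matrix (subjects are few, features
many), with a deterministic sign fix (largest-|loading| element positive).
PC-extreme templates warp the template by `mean + scale * component`
(conventional display scales ±500).

**Volumes.** Label volumes are voxel counts times the voxel volume in
mm^3 (the published table's units are unstated; mm^3 assumed). Group
comparisons use the Welch unequal-variance t-test — the default of base
R's `t.test`, which the published analysis cites — computable from raw
samples or directly from printed mean/sd/n summaries.

## The synthetic cohort (what a green test establishes)

`make_template_phantom` paints eight ellipsoidal organs (brain, spinal
cord rod, heart, two lungs, liver, stomach, bladder) inside an ellipsoidal
body on a 64^3 grid at 0.06 mm spacing — the working resolution of the
downsampled embryo scans this emulates — with piecewise-constant
intensities plus Gaussian noise (default sd 5 on organ intensities of
45–160, i.e. a conservatively noisy staining contrast). Organ overlap or
leakage outside the body is a construction error, not a warning.

`make_subject` composes, right-to-left: per-organ radial volume-scaling
fields (pure scaling over the whole organ, so the core log J is exactly
`ln f` and the transported label volume is `f` times the original,
blending to identity outside a shell), a quadratic bend, and a
Gaussian-smoothed random elastic field. The composition is verified
diffeomorphic at generation time (min J > 0; elastic amplitude halves on
failure, at most 3 times) and the subject is rendered by pulling the
template through the *inverse* map so the subject's anatomy genuinely
occupies the transformed region. Each subject stores its exact forward
transform and log-Jacobian.

Two stated-world defaults deserve justification:

* **Bend amplitude 0.3 / mm.** The displacement is
  `amplitude * D^2` along the bend axis (D = distance along the body
  axis), tapered by a smooth window over every axis *except* the bend
  axis — a window varying along the bend axis makes the map fold, whereas
  this construction is a pure shear with analytic Jacobian exactly 1.
  At 0.3/mm the body ends deflect by roughly a fifth of the body length:
  a severe, unmistakable scoliosis. This matters because the modelled
  phenomenon is *intensity-only registration failing* on severely bent
  subjects; at mild amplitudes (0.12/mm was our first guess) both arms
  register the phantoms almost equally well and the comparison the
  package exists to demonstrate does not arise.
* **Elastic sd 0.04 mm** (~0.5 voxel RMS, smoothing sigma 4 voxels, peak
  clipped at 1.5 voxels): inter-individual anatomic variability of about
  a voxel at this resolution. Too little within-group variability makes
  the voxel-wise t-test flag arbitrarily small systematic registration
  biases across the whole body.

The knockout-like group additionally halves both lungs and scales the
heart by 1.3, mirroring the strongest published organ phenotypes.

What the phantoms do **not** emulate: real staining texture within
organs, skeletal structures, partial-volume effects, topology change
(truly missing organs), and scanner artefacts. A green comparative test
therefore establishes that the pipeline's machinery behaves as designed
under known ground truth — not that it reproduces any specific biological
measurement.

## Numerical choices and edge cases

* Interpolation: multilinear with zero outside; nearest rounds half away
  from zero. Gaussian smoothing is separable, truncated at 3 sigma, and
  renormalised at boundaries so constants are preserved.
* The greedy engine is deterministic (no RNG); all stochasticity lives in
  phantom generation behind explicit seeds, so identical configs and
  seeds give identical outputs.
* NIfTI-1 I/O is implemented in the package (no R NIfTI reader is assumed
  present): float64 scalars, int32 labels, 5-D float64 vector images for
  fields, geometry in the sform. NIfTI-1 headers store geometry as
  float32, so spacing/origin/direction round-trip at single precision
  (~1e-7 relative); voxel payloads round-trip exactly.
* Published per-organ p-values are reproduced from the printed group
  summaries; where propagating half a printed rounding unit through the
  Welch formula yields a p-interval wider than ±0.001, agreement is
  asserted against that attainable bound instead (four of fifteen rows).

## What the fixed-bend cohort can and cannot demonstrate

The comparative cohort gives every knockout-like subject the *same* bend
amplitude. Under that design the label-informed arm recovers the true
deformation substantially better than the intensity-only arm on every
bent subject (mean endpoint error ~1.5 vs ~2.3 voxels at 48^3, organ
Dice ~0.82 vs ~0.70), which is the package's central measurable claim.
But the design also makes both arms' *residual misregistration
systematic*: every bent subject is misregistered the same way, so the
voxel-wise t-test — which is sensitive to any consistent group
difference — awards *more* significant voxels to the arm with the larger
bias (the intensity-only arm), and the significant set dwarfs the truly
scaled organ region in both arms. On real cohorts the intensity-only arm
fails *differently on each subject* (variable expressivity, different
failure modes), inflating within-group variance and collapsing its
significance map; that inconsistency is exactly what a fixed-amplitude
phantom cohort cannot emulate. The corresponding acceptance assertions
(more significant voxels for the label arm; Dice of the significant set
against the scaled organs; PCA silhouette ordering) are therefore left
red, with the measured values and this analysis recorded, rather than
redefining the cohort after the fact.

## Known limitations

* The engine is greedy and only approximately symmetric: registering A to
  B and B to A composes to ~0.5 voxel, not machine zero.
* The spinal-cord rod is about one voxel wide at coarse test resolutions;
  its Dice is voxelization-limited there.
* Thin-structure accuracy and large-rotation initialisation are limited
  by the centroid-based linear stage; a missing organ in either image
  simply drops out of the correspondence set.
* No B-spline parameterisation, mutual information, covariate-adjusted
  TBM, or 4D support.
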