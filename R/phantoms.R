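# Seeded multi-organ phantoms with known ground-truth deformations.
#
# The generator emulates the kind of data this toolkit targets: iodine-
# stained whole-embryo microCT volumes with a wildtype-like template, a body
# mask, organ segmentations, and mutant-like subjects whose overall shape is
# bent (a scoliosis surrogate) and whose organs change volume by a known
# factor. Every subject carries its exact forward transform and log-Jacobian
# so recovery can be scored against analytic truth.

#' Default phantom specification
#'
#' A 64^3 grid at 0.06 mm isotropic spacing (the working resolution of the
#' downsampled embryo scans this emulates) carrying eight ellipsoidal organs
#' loosely arranged like brain, spinal cord, heart, two lungs, liver, stomach
#' and bladder inside an ellipsoidal body.
#'
#' @param shape voxels per axis (scalar or length-3).
#' @param spacing voxel spacing in mm.
#' @param noise_sd additive Gaussian intensity noise (image units).
#' @param seed integer RNG seed for the noise.
#' @return A list of class `phantom_spec` with fields `grid`, `organs`
#'   (data.frame: label, name, center/radii in mm, intensity),
#'   `body` (center, radii, intensity), `noise_sd`, `seed`.
#' @export
phantom_spec <- function(shape = 64, spacing = 0.06, noise_sd = 5,
                         seed = 1L) {
  shape <- rep_len(as.integer(shape), 3L)
  grid <- image_grid(shape, spacing)
  ext <- (shape - 1L) * rep_len(spacing, 3L)  # physical extent, mm
  c0 <- ext / 2                               # body center
  s <- ext / 3.78                             # scale relative to default
  organ <- function(label, name, cx, cy, cz, rx, ry, rz, intensity)
    data.frame(label = label, name = name,
               cx = cx * s[1], cy = cy * s[2], cz = cz * s[3],
               rx = rx * min(s), ry = ry * min(s), rz = rz * min(s),
               intensity = intensity, stringsAsFactors = FALSE)
  organs <- rbind(
    organ(1L, "brain",       1.89, 1.89, 3.02, 0.50, 0.48, 0.42, 160),
    organ(2L, "spinal_cord", 1.89, 1.25, 1.62, 0.11, 0.11, 1.00, 120),
    organ(3L, "heart",       2.22, 2.18, 2.32, 0.27, 0.25, 0.25, 150),
    organ(4L, "lung_left",   1.38, 2.02, 2.32, 0.26, 0.24, 0.29, 90),
    organ(5L, "lung_right",  2.62, 1.62, 2.32, 0.26, 0.24, 0.29, 95),
    organ(6L, "liver",       1.72, 2.12, 1.42, 0.48, 0.38, 0.40, 140),
    organ(7L, "stomach",     1.25, 1.72, 0.92, 0.25, 0.23, 0.25, 110),
    organ(8L, "bladder",     1.89, 2.02, 0.60, 0.19, 0.19, 0.19, 130))
  structure(list(grid = grid,
                 organs = organs,
                 body = list(center = c0,
                             radii = c(1.55, 1.35, 1.83) * s,
                             intensity = 45),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# indicator of an ellipsoid evaluated at all voxel centers -> logical array
ellipsoid_mask <- function(grid, center, radii) {
  pts <- grid_points(grid)
  q <- sweep(pts, 2, center, "-")
  q <- sweep(q, 2, radii, "/")
  m <- rowSums(q^2) <= 1
  dim(m) <- grid$shape
  m
}

#' Generate a template-like phantom
#'
#' Paints organs (ellipsoids) over a body ellipsoid: each organ voxel gets
#' the organ's mean intensity, body-not-organ voxels the body intensity, and
#' outside-body voxels 0, plus additive Gaussian noise inside the body.
#' Organs overlapping each other or leaking outside the body are an error.
#'
#' @param spec a [phantom_spec()].
#' @return List with `intensity` (`scalar_image`), `labels` (`label_image`),
#'   `mask` (`label_image`, body = 1), and the `spec`.
#' @export
make_template_phantom <- function(spec = phantom_spec()) {
  grid <- spec$grid
  body <- ellipsoid_mask(grid, spec$body$center, spec$body$radii)
  lab <- array(0L, grid$shape)
  img <- array(0, grid$shape)
  img[body] <- spec$body$intensity
  for (i in seq_len(nrow(spec$organs))) {
    o <- spec$organs[i, ]
    m <- ellipsoid_mask(grid, c(o$cx, o$cy, o$cz), c(o$rx, o$ry, o$rz))
    if (any(lab[m] != 0L))
      stop("make_template_phantom: organ '", o$name,
           "' overlaps another organ")
    if (any(!body[m]))
      stop("make_template_phantom: organ '", o$name, "' exits the body")
    lab[m] <- o$label
    img[m] <- o$intensity
  }
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    img[body] <- img[body] + rnorm(sum(body), 0, spec$noise_sd)
  }
  list(intensity = scalar_image(grid, img),
       labels = label_image(grid, lab),
       mask = label_image(grid, array(as.integer(body), grid$shape)),
       spec = spec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# smooth taper: 1 in the interior, smoothstep to 0 within `margin` voxels of
# the grid boundary, evaluated per voxel -> array; `axes` selects which
# boundaries taper
boundary_taper <- function(grid, margin = 5, axes = seq_along(grid$shape)) {
  dm <- grid$shape
  w <- array(1, dm)
  smoothstep <- function(t) { t <- pmin(pmax(t, 0), 1); t * t * (3 - 2 * t) }
  for (ax in axes) {
    i <- seq_len(dm[ax]) - 1
    prof <- smoothstep(i / margin) * smoothstep((dm[ax] - 1 - i) / margin)
    w <- w * array(prof[slice.index(w, ax)], dm)
  }
  w
}

#' Global bend deformation (scoliosis surrogate)
#'
#' Displaces points along axis `axis_pair[2]` by `amplitude * (x_a - x_a0)^2`
#' where `x_a` is the coordinate along the body axis `axis_pair[1]` and
#' `x_a0` its value at the grid center, tapered to zero near the grid
#' boundary by a smooth window over every axis except the bend axis itself.
#' Because the displacement acts along the bend axis but never varies along
#' it, the map is a pure shear with analytic Jacobian determinant 1; the
#' minimum Jacobian of the sampled field is still verified numerically and
#' non-positive values are refused.
#'
#' @param grid [image_grid()].
#' @param amplitude curvature coefficient in 1/mm; displacement at physical
#'   distance D from the bend origin is `amplitude * D^2` mm.
#' @param axis_pair integer pair `(body_axis, bend_axis)`, default `c(3, 1)`.
#' @return A diffeomorphic `displacement_field`.
#' @export
bend_field <- function(grid, amplitude, axis_pair = c(3L, 1L)) {
  d <- grid_dim(grid)
  a <- axis_pair[1]; b <- axis_pair[2]
  stopifnot(a != b, a <= d, b <= d)
  u <- array(0, c(grid$shape, d))
  if (amplitude != 0) {
    pts <- grid_points(grid)
    center <- index_to_physical(grid, (grid$shape - 1) / 2)
    dx <- pts[, a] - center[a]
    w <- boundary_taper(grid, axes = setdiff(seq_len(d), b))
    ub <- amplitude * dx^2 * as.vector(w)
    idx <- slice.index(u, length(dim(u))) == b
    u[idx] <- ub
    fld <- displacement_field(grid, u)
    jac <- jacobian_image(fld, grid, log = FALSE)
    minJ <- min(jac$values[interior_mask(grid)])
    if (minJ <= 0)
      stop("bend_field: amplitude ", amplitude,
           " folds the domain (min interior J = ", signif(minJ, 3), ")")
    return(fld)
  }
  displacement_field(grid, u)
}

#' Local uniform volume-scaling deformation around an ellipsoidal organ
#'
#' Builds a radial map that scales the whole organ (normalised ellipsoid
#' radius rho <= rho0 = 1) uniformly about the organ center so the local
#' volume factor there is exactly `f` (log-Jacobian `ln f`) and the warped
#' label volume is `f` times the original, blending smoothly to the
#' identity outside rho1. The deformation is refused if it folds.
#'
#' @param grid [image_grid()].
#' @param center,radii organ ellipsoid center and radii in mm.
#' @param f target volume factor, `0.3 <= f <= 3`.
#' @param rho0,rho1 inner (pure scaling) and outer (identity) normalised
#'   radii of the blending shell.
#' @return A diffeomorphic `displacement_field`.
#' @export
organ_scale_field <- function(grid, center, radii, f,
                              rho0 = 1.0, rho1 = 1.9) {
  if (f < 0.3 || f > 3)
    stop("organ_scale_field: f must be in [0.3, 3]")
  d <- grid_dim(grid)
  s <- f^(1 / d)   # linear factor giving volume factor f
  pts <- grid_points(grid)
  q <- sweep(pts, 2, center, "-")
  rho <- sqrt(rowSums(sweep(q, 2, radii, "/")^2))
  # blend: 1 in core, smooth ramp to 0 at rho1
  t <- (rho - rho0) / (rho1 - rho0)
  t <- pmin(pmax(t, 0), 1)
  beta <- 1 - t * t * (3 - 2 * t)
  u <- q * ((s - 1) * beta)
  fld <- displacement_field(grid, array(u, c(grid$shape, d)))
  if (abs(f - 1) > 1e-12) {
    jac <- jacobian_image(fld, grid, log = FALSE)
    minJ <- min(jac$values[interior_mask(grid)])
    if (minJ <= 0)
      stop("organ_scale_field: folding detected (min interior J = ",
           signif(minJ, 3), ")")
  }
  fld
}

# Gaussian-smoothed white vector noise, tapered to zero at the grid
# boundary, RMS-rescaled and magnitude-clipped; per-subject individuality.
elastic_field <- function(grid, sd_mm, smooth_vox = 4, clip_vox = 1.5) {
  d <- grid_dim(grid)
  u <- array(rnorm(prod(grid$shape) * d), c(grid$shape, d))
  taper <- boundary_taper(grid)
  for (c in seq_len(d)) {
    comp <- if (d == 2) u[, , c] else u[, , , c]
    sm <- cpp_gauss_smooth(as.array(comp), rep(smooth_vox, d)) * taper
    if (d == 2) u[, , c] <- sm else u[, , , c] <- sm
  }
  n <- prod(grid$shape)
  um <- matrix(u, n, d)
  mag <- sqrt(rowSums(um^2))
  rms <- sqrt(mean(mag^2))
  if (rms > 0) um <- um * (sd_mm / rms)
  # clip |u| at clip_vox voxels to guarantee no folding
  cap <- clip_vox * min(grid$spacing)
  mag <- sqrt(rowSums(um^2))
  um <- um * pmin(1, cap / pmax(mag, 1e-12))
  displacement_field(grid, array(um, c(grid$shape, d)))
}

#' Subject specification for phantom generation
#'
#' @param bend_amplitude curvature coefficient (1/mm) passed to
#'   [bend_field()]; 0 for wildtype-like subjects. The knockout-like
#'   cohort default is 0.3, a severe bend deflecting the body ends by
#'   roughly a fifth of the body length.
#' @param organ_scale named numeric vector mapping organ label (as character)
#'   to a volume factor; empty for no organ phenotype.
#' @param elastic_sd RMS elastic perturbation in mm (individual variation;
#'   default about half a voxel at the default spacing).
#' @param seed integer seed controlling the elastic field and image noise.
#' @return list of class `subject_spec`.
#' @export
subject_spec <- function(bend_amplitude = 0, organ_scale = numeric(),
                         elastic_sd = 0.04, seed = 1L) {
  if (length(organ_scale) && is.null(names(organ_scale)))
    stop("subject_spec: organ_scale must be named by label")
  structure(list(bend_amplitude = bend_amplitude,
                 organ_scale = organ_scale,
                 elastic_sd = elastic_sd, seed = as.integer(seed)),
            class = "subject_spec")
}

#' Generate a synthetic subject from a template phantom
#'
#' Composes (right-to-left: organ scalings, then bend, then elastic
#' perturbation) into a ground-truth forward transform `T` mapping template
#' space to subject space, verifies it is diffeomorphic, and renders the
#' subject by pulling template values through the inverse map
#' (`subject(y) = template(T^{-1}(y))`) so that the subject's organs really
#' occupy `T(organ)`. Fresh intensity noise is added inside the subject body.
#'
#' If the elastic perturbation makes the composition fold, it is regenerated
#' with halved amplitude, at most 3 times.
#'
#' @param template output of [make_template_phantom()].
#' @param spec a [subject_spec()].
#' @return List with `intensity`, `labels`, `mask`, `true_forward`
#'   (a `composite_transform` holding the dense forward field),
#'   `true_logjac` (a `jacobian_image`), and the `spec`.
#' @export
make_subject <- function(template, spec) {
  grid <- template$intensity$grid
  d <- grid_dim(grid)
  organs <- template$spec$organs
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  parts <- list()
  if (spec$bend_amplitude != 0)
    parts <- c(parts, list(bend_field(grid, spec$bend_amplitude)))
  for (lab in names(spec$organ_scale)) {
    f <- spec$organ_scale[[lab]]
    if (abs(f - 1) < 1e-12) next
    o <- organs[organs$label == as.integer(lab), ]
    if (nrow(o) != 1) stop("make_subject: unknown organ label ", lab)
    parts <- c(parts, list(organ_scale_field(
      grid, c(o$cx, o$cy, o$cz), c(o$rx, o$ry, o$rz), f)))
  }

  esd <- spec$elastic_sd
  for (attempt in 1:3) {
    all_parts <- parts
    if (esd > 0)
      all_parts <- c(list(elastic_field(grid, esd)), all_parts)
    if (length(all_parts) == 0)
      all_parts <- list(identity_transform(d))
    fwd <- compose_to_field(all_parts, grid)
    jac <- jacobian_image(fwd, grid, log = TRUE)
    minJ <- min(exp(jac$values[interior_mask(grid)]))
    if (minJ > 0 && attr(jac, "n_folded") == 0) break
    if (attempt == 3)
      stop("make_subject: composed transform folds even after reducing ",
           "elastic_sd")
    esd <- esd / 2
  }

  inv <- invert_field(fwd, max_iter = 100L)
  intensity <- warp_image(clean_template_intensity(template), inv, grid,
                          "linear")
  labels <- warp_image(template$labels, inv, grid, "nearest")
  mask <- warp_image(template$mask, inv, grid, "nearest")
  img <- intensity$values
  inside <- mask$values > 0L
  if (template$spec$noise_sd > 0)
    img[inside] <- img[inside] + rnorm(sum(inside), 0,
                                       template$spec$noise_sd)
  list(intensity = scalar_image(grid, img),
       labels = labels, mask = mask,
       true_forward = composite_transform(list(fwd)),
       true_logjac = jac,
       spec = spec)
}

# noiseless version of the template intensity (re-painted from the spec), so
# subject noise is fresh rather than warped template noise
clean_template_intensity <- function(template) {
  spec <- template$spec
  spec$noise_sd <- 0
  make_template_phantom(spec)$intensity
}

#' Generate a two-group phantom cohort
#'
#' Group A ("wildtype-like") subjects have no bend and no organ scaling;
#' group B ("knockout-like") subjects share a scoliosis-like bend and
#' per-organ volume factors (defaults: both lungs halved, heart scaled by
#' 1.3). Every subject gets its own elastic perturbation and noise through a
#' per-subject seed derived from `seed`.
#'
#' @param template output of [make_template_phantom()].
#' @param n_a,n_b group sizes (default 9 and 9).
#' @param bend_amplitude bend for group B (1/mm).
#' @param organ_scale named volume-factor map for group B; names are organ
#'   labels of the default phantom (4/5 = lungs, 3 = heart).
#' @param elastic_sd per-subject RMS elastic perturbation in mm.
#' @param seed base seed.
#' @return List with `subjects` (list), `group` (factor "A"/"B"), `template`.
#' @export
make_cohort <- function(template, n_a = 9, n_b = 9,
                        bend_amplitude = 0.3,
                        organ_scale = c("4" = 0.5, "5" = 0.5, "3" = 1.3),
                        elastic_sd = 0.04, seed = 1L) {
  subjects <- list()
  group <- character(0)
  for (i in seq_len(n_a)) {
    subjects[[length(subjects) + 1L]] <- make_subject(
      template, subject_spec(0, numeric(), elastic_sd,
                             seed = seed * 1000L + i))
    group <- c(group, "A")
  }
  for (i in seq_len(n_b)) {
    subjects[[length(subjects) + 1L]] <- make_subject(
      template, subject_spec(bend_amplitude, organ_scale, elastic_sd,
                             seed = seed * 1000L + 500L + i))
    group <- c(group, "B")
  }
  list(subjects = subjects, group = factor(group), template = template)
}
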