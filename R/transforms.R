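# Spatial transforms map fixed-space physical points (mm) into moving-space
# physical points. Warping pulls moving-image values back onto the fixed
# (reference) grid through that map.

#' Create an affine transform
#'
#' Maps a point `x` to `matrix %*% (x - center) + center + translation`.
#'
#' @param matrix invertible d x d matrix.
#' @param translation d-vector (mm), default zero.
#' @param center center of rotation/scaling (mm), default zero.
#' @return Object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, translation = NULL, center = NULL) {
  matrix <- as.matrix(matrix)
  d <- nrow(matrix)
  if (ncol(matrix) != d) stop("affine_transform: matrix must be square")
  if (abs(det(matrix)) < 1e-12)
    stop("affine_transform: matrix must be invertible")
  if (is.null(translation)) translation <- rep(0, d)
  if (is.null(center)) center <- rep(0, d)
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = c("affine_transform", "spatial_transform"))
}

#' Identity transform of a given dimensionality
#' @param d dimensionality (2 or 3).
#' @export
identity_transform <- function(d = 3) affine_transform(diag(d))

#' Pure translation transform
#' @param t translation vector in mm.
#' @export
translation_transform <- function(t)
  affine_transform(diag(length(t)), translation = t)

#' Create a dense displacement field
#'
#' Maps `x` to `x + u(x)` with `u` stored per voxel in physical units (mm)
#' and sampled with multilinear interpolation between voxel centers; outside
#' the grid `u` is zero.
#'
#' @param grid an [image_grid()].
#' @param vectors numeric array of dim `c(grid$shape, d)`, finite.
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(grid, vectors) {
  d <- grid_dim(grid)
  vectors <- as.array(vectors)
  if (!identical(as.integer(dim(vectors)), c(grid$shape, d)))
    stop("displacement_field: vectors must have dim c(shape, d)")
  if (!all(is.finite(vectors)))
    stop("displacement_field: all components must be finite")
  storage.mode(vectors) <- "double"
  structure(list(grid = grid, vectors = vectors),
            class = c("displacement_field", "spatial_transform"))
}

zero_field <- function(grid) {
  d <- grid_dim(grid)
  displacement_field(grid, array(0, c(grid$shape, d)))
}

#' Compose transforms into a composite
#'
#' Transforms are applied right-to-left: `composite(list(A, B))` maps `x` to
#' `A(B(x))`.
#'
#' @param transforms list of `affine_transform` / `displacement_field` /
#'   `composite_transform` objects (composites are flattened).
#' @return Object of class `composite_transform`.
#' @export
composite_transform <- function(transforms) {
  if (inherits(transforms, "spatial_transform")) transforms <- list(transforms)
  flat <- list()
  for (t in transforms) {
    if (inherits(t, "composite_transform")) flat <- c(flat, t$transforms)
    else if (inherits(t, "spatial_transform")) flat <- c(flat, list(t))
    else stop("composite_transform: not a transform")
  }
  if (length(flat) == 0) stop("composite_transform: empty")
  ds <- vapply(flat, transform_dim, integer(1))
  if (length(unique(ds)) != 1)
    stop("composite_transform: mixed dimensionality")
  structure(list(transforms = flat),
            class = c("composite_transform", "spatial_transform"))
}

transform_dim <- function(t) {
  if (inherits(t, "affine_transform")) nrow(t$matrix)
  else if (inherits(t, "displacement_field")) grid_dim(t$grid)
  else if (inherits(t, "composite_transform")) transform_dim(t$transforms[[1]])
  else stop("not a transform")
}

# Sample one component array of a field at physical points (matrix n x d).
sample_field_component <- function(field, comp, points) {
  d <- grid_dim(field$grid)
  idx <- physical_to_continuous_index(field$grid, points)
  vals <- if (d == 2) field$vectors[, , comp] else field$vectors[, , , comp]
  cpp_interp(as.array(vals), idx, FALSE, 0)
}

#' Apply a transform to physical points
#'
#' @param transform any spatial transform.
#' @param points n x d matrix of physical points (mm), or a single d-vector.
#' @return Mapped points, same shape as input.
#' @export
apply_transform <- function(transform, points) {
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(as.numeric(points), nrow = 1) else as.matrix(points)
  if (ncol(pts) != transform_dim(transform))
    stop("apply_transform: dimensionality mismatch")
  out <- apply_transform_impl(transform, pts)
  if (vec) drop(out) else out
}

apply_transform_impl <- function(transform, pts) {
  UseMethod("apply_transform_impl")
}

#' @export
apply_transform_impl.affine_transform <- function(transform, pts) {
  ctr <- sweep(pts, 2, transform$center, "-") %*% t(transform$matrix)
  sweep(ctr, 2, transform$center + transform$translation, "+")
}

#' @export
apply_transform_impl.displacement_field <- function(transform, pts) {
  d <- ncol(pts)
  u <- vapply(seq_len(d),
              function(c) sample_field_component(transform, c, pts),
              numeric(nrow(pts)))
  pts + u
}

#' @export
apply_transform_impl.composite_transform <- function(transform, pts) {
  for (t in rev(transform$transforms)) pts <- apply_transform_impl(t, pts)
  pts
}

#' Invert an affine transform
#' @param transform an `affine_transform`.
#' @export
invert_affine <- function(transform) {
  Mi <- solve(transform$matrix)
  # y = M (x - c) + c + t  =>  x = Mi (y - c - t) + c
  affine_transform(Mi,
                   translation = -drop(Mi %*% transform$translation),
                   center = transform$center + transform$translation)
}

#' Warp an image through a transform onto a reference grid
#'
#' Computes `output(x) = moving(T(x))` at every reference voxel center, i.e.
#' pulls moving-image values back onto the fixed grid. Samples falling
#' outside the moving image return 0 (background).
#'
#' @param moving a `scalar_image` or `label_image`.
#' @param transform transform mapping reference-space points into
#'   moving-image space.
#' @param reference target [image_grid()]; defaults to the moving grid.
#' @param interpolation `"linear"` or `"nearest"`; labels must use nearest.
#' @return Image of the same class as `moving`, on `reference`.
#' @export
warp_image <- function(moving, transform, reference = moving$grid,
                       interpolation = if (is_label_image(moving)) "nearest"
                       else "linear") {
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  if (is_label_image(moving) && interpolation != "nearest")
    stop("warp_image: label images require nearest interpolation")
  if (transform_dim(transform) != grid_dim(reference))
    stop("warp_image: transform dimensionality mismatch")
  pts <- grid_points(reference)
  mapped <- apply_transform(transform, pts)
  idx <- physical_to_continuous_index(moving$grid, mapped)
  vals <- cpp_interp(moving$values * 1.0, idx, interpolation == "nearest", 0)
  dim(vals) <- reference$shape
  if (is_label_image(moving)) label_image(reference, vals)
  else scalar_image(reference, vals)
}

#' Collapse a composite transform to a dense displacement field
#'
#' Evaluates `u(x) = T(x) - x` at every voxel center of the reference grid.
#'
#' @param transforms a transform or list of transforms (applied
#'   right-to-left).
#' @param reference [image_grid()] on which to sample the field.
#' @return A `displacement_field` on `reference`.
#' @export
compose_to_field <- function(transforms, reference) {
  ct <- composite_transform(transforms)
  pts <- grid_points(reference)
  u <- apply_transform(ct, pts) - pts
  displacement_field(reference, array(u, c(reference$shape, ncol(u))))
}

#' Invert a displacement field by fixed-point iteration
#'
#' Iterates `v_{k+1}(x) = -u(x + v_k(x))` until the composition residual
#' `max |u(x + v(x)) + v(x)|` drops below `tol`. The input must be
#' diffeomorphic (positive Jacobian) for convergence.
#'
#' @param field a `displacement_field`.
#' @param tol residual tolerance in mm; default `0.01 * min(spacing)`.
#' @param max_iter maximum iterations.
#' @return A `displacement_field` with attributes `residual` (achieved mm)
#'   and `converged` (logical); non-convergence is flagged, not an error.
#' @export
invert_field <- function(field, tol = 0.01 * min(field$grid$spacing),
                         max_iter = 50L) {
  grid <- field$grid
  d <- grid_dim(grid)
  pts <- grid_points(grid)
  nv <- nrow(pts)
  v <- matrix(0, nv, d)
  # damped fixed-point iteration v <- v + omega * (-u(x+v) - v); the
  # undamped map contracts only for small displacement gradients, so the
  # damping adapts: halve omega whenever the residual worsens.
  omega <- 1
  best_v <- v
  best_mean <- Inf
  best_max <- Inf
  for (iter in seq_len(max_iter)) {
    q <- pts + v
    u_at <- vapply(seq_len(d),
                   function(c) sample_field_component(field, c, q),
                   numeric(nv))
    err <- u_at + v
    rs <- sqrt(rowSums(err^2))
    mean_resid <- mean(rs)
    if (mean_resid < best_mean) {
      best_mean <- mean_resid
      best_max <- max(rs)
      best_v <- v
    } else if (mean_resid > best_mean) {
      omega <- omega / 2
      v <- best_v
      if (omega < 1 / 64) break
      next
    }
    if (max(rs) <= tol) break
    v <- v - omega * err
  }
  out <- displacement_field(grid, array(best_v, c(grid$shape, d)))
  attr(out, "residual") <- best_max
  attr(out, "converged") <- best_max <= tol
  out
}

# Shift an array by +1/-1 voxel along one axis, replicating the edge
# (supports one-sided differences at boundaries).
shift_array <- function(a, axis, by) {
  dm <- dim(a)
  idx <- lapply(dm, seq_len)
  src <- pmin(pmax(idx[[axis]] - by, 1L), dm[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Gradient of one scalar array wrt index along each axis (central differences
# interior, one-sided at boundaries). Returns list of arrays per axis.
index_gradient <- function(a) {
  dm <- dim(a)
  d <- length(dm)
  lapply(seq_len(d), function(ax) {
    fwd <- shift_array(a, ax, -1L)   # value at i+1 (edge-replicated)
    bwd <- shift_array(a, ax, +1L)   # value at i-1
    den <- array(2, dm)
    # boundary slabs use one-sided differences: spacing denominator 1
    idx <- lapply(dm, seq_len)
    for (side in c(1L, dm[ax])) {
      ii <- idx; ii[[ax]] <- side
      den_idx <- as.matrix(do.call(expand.grid, ii))
      den[den_idx] <- 1
    }
    (fwd - bwd) / den
  })
}

#' Jacobian determinant image of a transform
#'
#' Computes the determinant of the spatial derivative of the composed
#' transform at every reference voxel, via central differences of the dense
#' displacement field in physical coordinates (one-sided at boundaries). The
#' default returns the natural-log determinant, the quantity analysed in
#' tensor-based morphometry; `log J = 0` means no local volume change and
#' `log J < 0` local shrinkage.
#'
#' @param transform transform (or list) to differentiate.
#' @param reference [image_grid()] over which to evaluate.
#' @param log if `TRUE` (default) return `ln J`; non-positive determinants
#'   become `-Inf` and are counted in the `n_folded` attribute.
#' @return A `scalar_image`-like object of class `jacobian_image` with
#'   attribute `n_folded`.
#' @export
jacobian_image <- function(transform, reference, log = TRUE) {
  fld <- if (inherits(transform, "displacement_field") &&
             grid_equal(transform$grid, reference)) transform
  else compose_to_field(transform, reference)
  d <- grid_dim(reference)
  dm <- reference$shape
  # derivative of the map T(x) = x + u(x) wrt physical coordinates:
  # dT/dx = I + du/didx %*% (direction %*% diag(spacing))^-1
  A <- reference$direction %*% diag(reference$spacing, d)
  Ainv <- solve(A)
  n <- prod(dm)
  # G[[i]][[j]] = d u_i / d index_j as flat vectors
  G <- lapply(seq_len(d), function(ci) {
    comp <- if (d == 2) fld$vectors[, , ci] else fld$vectors[, , , ci]
    index_gradient(as.array(comp))
  })
  # Assemble Jacobian matrices per voxel: J_ij = delta_ij + sum_k G_ik Ainv_kj
  Jm <- vector("list", d)
  for (i in seq_len(d)) {
    Jm[[i]] <- vector("list", d)
    for (j in seq_len(d)) {
      acc <- if (i == j) rep(1, n) else rep(0, n)
      for (k in seq_len(d)) acc <- acc + as.vector(G[[i]][[k]]) * Ainv[k, j]
      Jm[[i]][[j]] <- acc
    }
  }
  detJ <- if (d == 2) {
    Jm[[1]][[1]] * Jm[[2]][[2]] - Jm[[1]][[2]] * Jm[[2]][[1]]
  } else {
    Jm[[1]][[1]] * (Jm[[2]][[2]] * Jm[[3]][[3]] - Jm[[2]][[3]] * Jm[[3]][[2]]) -
    Jm[[1]][[2]] * (Jm[[2]][[1]] * Jm[[3]][[3]] - Jm[[2]][[3]] * Jm[[3]][[1]]) +
    Jm[[1]][[3]] * (Jm[[2]][[1]] * Jm[[3]][[2]] - Jm[[2]][[2]] * Jm[[3]][[1]])
  }
  n_folded <- sum(detJ <= 0)
  vals <- if (log) base::log(pmax(detJ, 0)) else detJ
  dim(vals) <- dm
  out <- structure(list(grid = reference, values = vals),
                   class = c("jacobian_image", "scalar_image",
                             "spatial_image"))
  attr(out, "n_folded") <- n_folded
  attr(out, "log") <- log
  out
}

# interior (non-boundary) voxel mask of a grid, as a logical array
interior_mask <- function(grid, margin = 1L) {
  dm <- grid$shape
  d <- length(dm)
  m <- array(TRUE, dm)
  for (ax in seq_len(d)) {
    idx <- lapply(dm, seq_len)
    keep <- seq_len(dm[ax]) > margin & seq_len(dm[ax]) <= dm[ax] - margin
    idx[[ax]] <- which(!keep)
    if (length(idx[[ax]])) {
      grid_idx <- as.matrix(do.call(expand.grid, idx))
      m[grid_idx] <- FALSE
    }
  }
  m
}
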