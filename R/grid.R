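# Physical-space sampling model: every image and dense field lives on an
# ImageGrid that maps 0-based voxel indices to physical points (mm) through
# origin + direction %*% (spacing * index), with voxel-center convention.

#' Create an image grid
#'
#' An `image_grid` describes the physical sampling lattice shared by images
#' and displacement fields: array shape, voxel spacing in mm, the physical
#' position of voxel `(0, ..., 0)` (voxel centers), and an orthonormal
#' direction matrix. Dimensionality 2 or 3.
#'
#' @param shape integer vector of voxels per axis (length 2 or 3).
#' @param spacing physical voxel size per axis in mm, strictly positive.
#'   Scalars are recycled.
#' @param origin physical coordinate (mm) of the center of the first voxel.
#' @param direction orthonormal d x d matrix mapping index axes to physical
#'   axes; defaults to the identity.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(shape, spacing = 1, origin = 0, direction = NULL) {
  shape <- as.integer(shape)
  d <- length(shape)
  if (!(d %in% c(2L, 3L))) stop("image_grid: dimensionality must be 2 or 3")
  if (any(shape < 1L)) stop("image_grid: shape must be positive")
  spacing <- rep_len(as.numeric(spacing), d)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_grid: spacing must be strictly positive")
  origin <- rep_len(as.numeric(origin), d)
  if (is.null(direction)) direction <- diag(d)
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(d, d)))
    stop("image_grid: direction must be d x d")
  if (max(abs(crossprod(direction) - diag(d))) > 1e-8)
    stop("image_grid: direction must be orthonormal")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_grid")
}

grid_dim <- function(grid) length(grid$shape)

grid_equal <- function(a, b, tol = 1e-8) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' @export
print.image_grid <- function(x, ...) {
  cat("image_grid:", paste(x$shape, collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm\n")
  invisible(x)
}

#' Map voxel indices to physical coordinates
#'
#' Applies the voxel-center convention `origin + direction %*% (spacing *
#' index)` with 0-based indices.
#'
#' @param grid an [image_grid()].
#' @param index a 0-based integer index vector, or an n x d matrix of indices
#'   (one per row).
#' @return A physical point (mm) as a vector, or an n x d matrix of points.
#' @export
index_to_physical <- function(grid, index) {
  vec <- is.null(dim(index))
  idx <- if (vec) matrix(as.numeric(index), nrow = 1) else
    as.matrix(index)
  if (ncol(idx) != grid_dim(grid))
    stop("index_to_physical: index dimensionality mismatch")
  lo <- sweep(idx, 2, grid$shape - 1L, "-")
  if (any(idx < 0) || any(lo > 0))
    stop("index_to_physical: index out of range")
  p <- sweep(idx, 2, grid$spacing, "*") %*% t(grid$direction)
  p <- sweep(p, 2, grid$origin, "+")
  if (vec) drop(p) else p
}

# Inverse of index_to_physical for arbitrary physical points; returns
# continuous (possibly out-of-range) 0-based index coordinates.
physical_to_continuous_index <- function(grid, points) {
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(as.numeric(points), nrow = 1) else as.matrix(points)
  q <- sweep(pts, 2, grid$origin, "-") %*% grid$direction  # t(dir) = dir^-1
  q <- sweep(q, 2, grid$spacing, "/")
  if (vec) drop(q) else q
}

# n_voxels x d matrix of all 0-based indices in array (column-major) order.
grid_index_matrix <- function(grid) {
  d <- grid_dim(grid)
  args <- lapply(grid$shape, function(n) seq.int(0L, n - 1L))
  as.matrix(do.call(expand.grid, args))
}

# Physical voxel centers for every voxel, array order. Cached computation is
# cheap enough not to memoise.
grid_points <- function(grid) {
  index_to_physical(grid, grid_index_matrix(grid))
}

grid_voxel_volume <- function(grid) prod(grid$spacing)

#' Create a scalar (intensity) image
#'
#' @param grid an [image_grid()].
#' @param values numeric array with dim equal to the grid shape, all finite.
#' @return Object of class `scalar_image`.
#' @export
scalar_image <- function(grid, values) {
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("scalar_image: values shape must equal grid shape")
  if (!all(is.finite(values)))
    stop("scalar_image: all values must be finite")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values),
            class = c("scalar_image", "spatial_image"))
}

#' Create a label (segmentation) image
#'
#' Integer-valued image where 0 is background and positive integers identify
#' anatomical regions.
#'
#' @param grid an [image_grid()].
#' @param values non-negative integer array with dim equal to the grid shape.
#' @return Object of class `label_image`.
#' @export
label_image <- function(grid, values) {
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("label_image: values shape must equal grid shape")
  iv <- as.integer(round(values))
  if (any(!is.finite(values)) || max(abs(values - iv)) > 1e-6)
    stop("label_image: values must be integers")
  if (any(iv < 0L)) stop("label_image: labels must be non-negative")
  dim(iv) <- dim(values)
  structure(list(grid = grid, values = iv),
            class = c("label_image", "spatial_image"))
}

is_label_image <- function(x) inherits(x, "label_image")

#' Labels present in a label image (background 0 excluded)
#' @param labels a [label_image()].
#' @return sorted integer vector of nonzero labels.
#' @export
label_set <- function(labels) {
  stopifnot(is_label_image(labels))
  u <- sort(unique(as.vector(labels$values)))
  u[u != 0L]
}

#' @export
print.spatial_image <- function(x, ...) {
  cat(class(x)[1], "on ", sep = "")
  print(x$grid)
  invisible(x)
}

#' Resample an image to a new voxel spacing
#'
#' The new shape is `ceiling(shape * spacing / target_spacing)` so the
#' physical extent is preserved to within one voxel; origin and direction are
#' unchanged. Label images require nearest-neighbour interpolation.
#'
#' @param image a `scalar_image` or `label_image`.
#' @param target_spacing new spacing per axis in mm (scalar recycled).
#' @param interpolation `"linear"` or `"nearest"`; defaults to linear for
#'   scalar images and nearest for label images.
#' @return Image of the same class on the resampled grid.
#' @export
resample <- function(image, target_spacing,
                     interpolation = if (is_label_image(image)) "nearest"
                     else "linear") {
  grid <- image$grid
  d <- grid_dim(grid)
  target_spacing <- rep_len(as.numeric(target_spacing), d)
  if (any(target_spacing <= 0)) stop("resample: target_spacing must be > 0")
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  if (is_label_image(image) && interpolation != "nearest")
    stop("resample: label images require nearest interpolation")
  new_shape <- as.integer(ceiling(grid$shape * grid$spacing / target_spacing))
  new_grid <- image_grid(new_shape, target_spacing, grid$origin,
                         grid$direction)
  warp_image(image, identity_transform(d), new_grid, interpolation)
}
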