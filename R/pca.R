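# Multichannel PCA on stacked displacement fields: each subject's combined
# inverse field, sampled on the template grid inside the body mask, becomes
# one row (all d components of all masked voxels); PCA of those rows places
# subjects in a low-dimensional morphospace.

#' Stack displacement fields into a subjects x features matrix
#'
#' @param fields list of `displacement_field`s on one grid.
#' @param mask optional `label_image`; features restricted to mask > 0.
#' @return List with `matrix` (n x (d * n_masked)), and bookkeeping `grid`,
#'   `mask_idx` (masked voxel indices) for reshaping back.
#' @export
stack_fields <- function(fields, mask = NULL) {
  if (length(fields) == 0) stop("stack_fields: no fields")
  grid <- fields[[1]]$grid
  d <- grid_dim(grid)
  nvox <- prod(grid$shape)
  mask_idx <- if (!is.null(mask)) which(as.vector(mask$values > 0)) else
    seq_len(nvox)
  X <- t(vapply(fields, function(f) {
    if (!grid_equal(f$grid, grid)) stop("stack_fields: grids differ")
    as.vector(matrix(f$vectors, nvox, d)[mask_idx, ])
  }, numeric(length(mask_idx) * d)))
  list(matrix = X, grid = grid, mask_idx = mask_idx, d = d)
}

# inverse of stack_fields for one feature vector
unstack_field <- function(v, bookkeeping) {
  grid <- bookkeeping$grid
  d <- bookkeeping$d
  nvox <- prod(grid$shape)
  u <- matrix(0, nvox, d)
  u[bookkeeping$mask_idx, ] <- matrix(v, ncol = d)
  displacement_field(grid, array(u, c(grid$shape, d)))
}

#' PCA of stacked displacement fields
#'
#' Column-mean centering followed by the singular value decomposition of
#' the centered matrix; because subjects are few and features many, the
#' decomposition runs on the n x n Gram matrix. Component k explains
#' variance `s_k^2 / (n - 1)`. Each component's sign is fixed
#' deterministically so its largest-magnitude loading is positive.
#'
#' @param stacked output of [stack_fields()] (or a plain matrix).
#' @return List of class `field_pca` with `mean_field`, `components`
#'   (list of unit-norm `displacement_field`s), `eigenvalues`
#'   (non-increasing), `scores` (n x k), `sdev`, and the bookkeeping needed
#'   to reshape.
#' @export
fit_pca <- function(stacked) {
  bk <- NULL
  if (is.list(stacked) && !is.null(stacked$matrix)) {
    bk <- stacked
    X <- stacked$matrix
  } else X <- as.matrix(stacked)
  n <- nrow(X)
  if (n < 2) stop("fit_pca: need at least 2 subjects")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  G <- tcrossprod(Xc)                     # n x n
  eg <- eigen(G, symmetric = TRUE)
  tolv <- 1e-12 * max(eg$values, 0)
  keep <- which(eg$values > pmax(tolv, 1e-30))
  keep <- keep[seq_len(min(length(keep), n - 1))]
  rank0 <- length(keep) == 0
  if (rank0) {
    warning("fit_pca: all rows identical; zero components")
    keep <- integer(0)
  }
  s <- sqrt(pmax(eg$values[keep], 0))     # singular values
  V <- if (length(keep))
    crossprod(Xc, eg$vectors[, keep, drop = FALSE]) %*%
      diag(1 / s, length(keep)) else
    matrix(0, ncol(X), 0)
  # deterministic sign: largest-|loading| element positive
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  scores <- Xc %*% V
  eigenvalues <- s^2 / (n - 1)
  comps <- if (!is.null(bk))
    lapply(seq_len(ncol(V)), function(k) unstack_field(V[, k], bk)) else
    lapply(seq_len(ncol(V)), function(k) V[, k])
  mean_field <- if (!is.null(bk)) unstack_field(mu, bk) else mu
  structure(list(mean_field = mean_field, components = comps,
                 loadings = V, eigenvalues = eigenvalues,
                 scores = scores, sdev = sqrt(eigenvalues),
                 center = mu, bookkeeping = bk, rank0 = rank0),
            class = "field_pca")
}

#' @export
print.field_pca <- function(x, ...) {
  cat("field_pca:", length(x$eigenvalues), "components;",
      "variance explained:",
      paste0(signif(100 * x$eigenvalues /
                      max(sum(x$eigenvalues), 1e-30), 3)[
                        seq_len(min(3, length(x$eigenvalues)))],
             "%", collapse = ", "), "\n")
  invisible(x)
}

#' Warp the template to a PC extreme
#'
#' Applies `mean_field + scale * component_k` as a fixed-space displacement
#' to the template image, visualising the deformation mode. The synthesized
#' field is exactly linear in `scale`; the conventional display scales are
#' -500 and +500 (score units).
#'
#' @param template `scalar_image` on the PCA grid.
#' @param result a `field_pca` fitted from fields (not a bare matrix).
#' @param comp_index 1-based component index.
#' @param scale scalar multiple of the unit-norm component.
#' @return warped `scalar_image`; a warning is emitted (not an error) if
#'   the synthesized field folds.
#' @export
synthesize_pc_extreme <- function(template, result, comp_index,
                                  scale = 500) {
  if (is.null(result$bookkeeping))
    stop("synthesize_pc_extreme: PCA was not fitted from fields")
  if (comp_index < 1 || comp_index > length(result$components))
    stop("synthesize_pc_extreme: comp_index out of range")
  grid <- result$bookkeeping$grid
  u <- result$mean_field$vectors +
    scale * result$components[[comp_index]]$vectors
  fld <- displacement_field(grid, u)
  jac <- jacobian_image(fld, grid, log = FALSE)
  if (min(jac$values[interior_mask(grid)]) <= 0)
    warning("synthesize_pc_extreme: synthesized field folds; rendering ",
            "anyway")
  warp_image(template, fld, grid, "linear")
}

#' Silhouette-style group separation of PCA scores
#'
#' Mean silhouette width of the two-group partition in the space of the
#' selected score columns (Euclidean distance), plus, per component, whether
#' a threshold on that score alone separates the groups perfectly.
#'
#' @param scores n x k score matrix.
#' @param group two-level factor of length n.
#' @param pcs score columns to use (default first two).
#' @return List with `silhouette` (mean width) and `linear_separable`
#'   (logical per selected PC).
#' @export
pc_group_separation <- function(scores, group, pcs = 1:2) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2, nrow(scores) == length(group))
  pcs <- pcs[pcs <= ncol(scores)]
  S <- scores[, pcs, drop = FALSE]
  D <- as.matrix(dist(S))
  n <- nrow(S)
  sil <- vapply(seq_len(n), function(i) {
    own <- group == group[i]; own[i] <- FALSE
    a <- mean(D[i, own])
    b <- mean(D[i, group != group[i]])
    if (sum(own) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  sep <- vapply(pcs, function(k) {
    x <- scores[, k]
    max(x[group == levels(group)[1]]) < min(x[group == levels(group)[2]]) ||
      max(x[group == levels(group)[2]]) < min(x[group == levels(group)[1]])
  }, logical(1))
  list(silhouette = mean(sil), linear_separable = sep)
}
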