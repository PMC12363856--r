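# Stage-1 linear alignment. The label-informed arm fits a linear map from
# the centers of mass of corresponding label maps; the intensity-only arm
# minimises a masked mean-squared intensity difference over the parameters
# of the same linear models.

#' Centers of mass of label regions
#'
#' @param labels a [label_image()].
#' @param weights optional named numeric vector (names = label ids) of
#'   per-label weights; defaults to 1 per label so small organs anchor as
#'   strongly as large ones. `weights = "count"` uses voxel counts.
#' @return A data.frame of class `centroid_table` with columns `label`,
#'   one centroid column per axis (`c1..cd`, mm), `count`, `weight`.
#' @export
label_centroids <- function(labels, weights = NULL) {
  stopifnot(is_label_image(labels))
  labs <- label_set(labels)
  if (length(labs) == 0) stop("label_centroids: no nonzero labels")
  d <- grid_dim(labels$grid)
  pts <- grid_points(labels$grid)
  v <- as.vector(labels$values)
  cen <- matrix(NA_real_, length(labs), d)
  cnt <- integer(length(labs))
  for (i in seq_along(labs)) {
    sel <- v == labs[i]
    cnt[i] <- sum(sel)
    cen[i, ] <- colMeans(pts[sel, , drop = FALSE])
  }
  w <- rep(1, length(labs))
  if (identical(weights, "count")) w <- as.numeric(cnt)
  else if (!is.null(weights)) {
    m <- match(as.character(labs), names(weights))
    w[!is.na(m)] <- as.numeric(weights[m[!is.na(m)]])
  }
  if (any(w < 0)) stop("label_centroids: weights must be >= 0")
  out <- data.frame(label = labs, cen, count = cnt, weight = w)
  names(out)[2:(1 + d)] <- paste0("c", seq_len(d))
  class(out) <- c("centroid_table", "data.frame")
  out
}

centroid_matrix <- function(tab) {
  d <- sum(grepl("^c[0-9]+$", names(tab)))
  as.matrix(tab[, paste0("c", seq_len(d)), drop = FALSE])
}

# weighted rank of a centered point cloud (for degeneracy detection)
points_rank <- function(X, w, tol = 1e-9) {
  mu <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2, mu, "-") * sqrt(w)
  s <- svd(Xc)$d
  sum(s > tol * max(s, 1))
}

#' Fit a linear transform from corresponding label centroids
#'
#' Weighted least-squares fit mapping fixed-image centroids to moving-image
#' centroids. `"rigid"` uses weighted orthogonal Procrustes with a proper
#' rotation enforced, `"similarity"` adds a single isotropic scale (Umeyama),
#' `"affine"` solves weighted normal equations, `"translation"` matches the
#' weighted means. If the centroid geometry cannot support the requested
#' model (too few or degenerate points), the fit falls back to the richest
#' well-posed model and flags it.
#'
#' @param fixed,moving `centroid_table`s (see [label_centroids()]); only
#'   shared labels are used, with weights multiplied.
#' @param model `"rigid"`, `"similarity"`, `"affine"` or `"translation"`.
#' @return List of class `linear_fit` with `transform`
#'   (an `affine_transform` mapping fixed space to moving space), `model`
#'   (the model actually fitted), `requested`, `fallback` (logical),
#'   `rms_residual` (mm), `labels_used`.
#' @export
fit_linear_from_centroids <- function(fixed, moving,
                                      model = c("affine", "similarity",
                                                "rigid", "translation")) {
  model <- match.arg(model)
  shared <- intersect(fixed$label, moving$label)
  if (length(shared) == 0)
    stop("fit_linear_from_centroids: no shared labels")
  fi <- fixed[match(shared, fixed$label), ]
  mo <- moving[match(shared, moving$label), ]
  F <- centroid_matrix(fi)
  M <- centroid_matrix(mo)
  d <- ncol(F)
  w <- fi$weight * mo$weight
  if (sum(w) <= 0) stop("fit_linear_from_centroids: all weights zero")
  w <- w / sum(w)
  n <- length(shared)
  rank <- points_rank(F, w)

  # richest well-posed model given n points of given geometric rank
  feasible <- function(m) {
    switch(m,
           translation = TRUE,
           rigid = n >= 2 && rank >= d - 1,
           similarity = n >= 2 && rank >= d - 1,
           affine = n >= d + 1 && rank == d)
  }
  order_models <- c("affine", "similarity", "rigid", "translation")
  fitted_model <- model
  while (!feasible(fitted_model)) {
    pos <- match(fitted_model, order_models)
    fitted_model <- order_models[pos + 1L]
  }

  fbar <- colSums(F * w)
  mbar <- colSums(M * w)
  Fc <- sweep(F, 2, fbar, "-")
  Mc <- sweep(M, 2, mbar, "-")

  A <- diag(d)
  if (fitted_model %in% c("rigid", "similarity")) {
    H <- crossprod(Fc * w, Mc)          # sum w f' m'^T, d x d
    sv <- svd(H)
    D <- diag(d)
    D[d, d] <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% D %*% t(sv$u)         # proper rotation, M ~ R F
    A <- R
    if (fitted_model == "similarity") {
      denom <- sum(w * rowSums(Fc^2))
      s <- sum(diag(D) * sv$d) / denom
      A <- s * R
    }
  } else if (fitted_model == "affine") {
    # minimise sum w |A f' - m'|^2  =>  A = (sum w m'f'^T)(sum w f'f'^T)^-1
    A <- t(solve(crossprod(Fc * w, Fc), crossprod(Fc * w, Mc)))
  }

  # map: x -> A (x - fbar) + fbar + t, with t making fbar -> mbar
  tr <- affine_transform(A, translation = mbar - fbar, center = fbar)
  pred <- apply_transform(tr, F)
  rms <- sqrt(sum(w * rowSums((pred - M)^2)))
  structure(list(transform = tr, model = fitted_model, requested = model,
                 fallback = fitted_model != model,
                 rms_residual = rms, labels_used = shared),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("linear_fit:", x$model,
      if (x$fallback) paste0("(fallback from ", x$requested, ")") else "",
      "rms residual", signif(x$rms_residual, 4), "mm on",
      length(x$labels_used), "labels\n")
  invisible(x)
}

# build an affine from a flat parameter vector for a given model
params_to_affine <- function(par, model, d, center) {
  if (model == "translation") {
    A <- diag(d); t <- par
  } else if (model == "rigid" || model == "similarity") {
    if (d == 2) {
      th <- par[1]
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      k <- 1
    } else {
      # small-angle-friendly Euler composition about x, y, z
      cx <- cos(par[1]); sx <- sin(par[1])
      cy <- cos(par[2]); sy <- sin(par[2])
      cz <- cos(par[3]); sz <- sin(par[3])
      Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
      Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
      Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
      R <- Rz %*% Ry %*% Rx
      k <- 3
    }
    s <- if (model == "similarity") exp(par[k + 1]) else 1
    A <- s * R
    t <- par[(k + (model == "similarity") + 1):length(par)]
  } else {  # affine: d*d matrix entries (as I + dA) then translation
    A <- diag(d) + matrix(par[seq_len(d * d)], d, d)
    t <- par[(d * d + 1):length(par)]
  }
  affine_transform(A, translation = t, center = center)
}

n_params <- function(model, d) {
  switch(model,
         translation = d,
         rigid = if (d == 2) 1 + d else 3 + d,
         similarity = if (d == 2) 2 + d else 4 + d,
         affine = d * d + d)
}

#' Intensity-driven linear registration
#'
#' Multi-resolution (default 3 levels, downsampling factor 2) minimisation of
#' the masked mean-squared intensity difference over the parameters of the
#' requested linear model, using deterministic Nelder-Mead restarts per
#' level. Initialised at the translation aligning the mask (or image)
#' centers of mass.
#'
#' @param fixed,moving `scalar_image`s overlapping in physical space.
#' @param mask optional `label_image` on the fixed grid (metric restricted
#'   to mask > 0).
#' @param model linear model as in [fit_linear_from_centroids()].
#' @param levels number of resolution levels.
#' @param maxit Nelder-Mead iteration budget per level.
#' @return A `linear_fit` (rms_residual here is the final RMS masked
#'   intensity difference, image units).
#' @export
intensity_linear_register <- function(fixed, moving, mask = NULL,
                                      model = c("affine", "similarity",
                                                "rigid", "translation"),
                                      levels = 3L, maxit = 200L) {
  model <- match.arg(model)
  d <- grid_dim(fixed$grid)
  if (!is.null(mask) && sum(mask$values > 0) == 0)
    stop("intensity_linear_register: empty mask")

  # initial translation: identity when a mask is given (the moving image
  # may contain arbitrary values outside the subject), otherwise the
  # intensity centers-of-mass offset
  com <- function(img, msk) {
    pts <- grid_points(img$grid)
    wgt <- if (!is.null(msk)) as.numeric(msk$values > 0) else
      pmax(as.vector(img$values), 0)
    if (sum(wgt) == 0) wgt <- rep(1, nrow(pts))
    colSums(pts * wgt) / sum(wgt)
  }
  cf <- com(fixed, mask)
  center <- cf
  np <- n_params(model, d)
  par0 <- rep(0, np)
  if (is.null(mask))
    par0[(np - d + 1):np] <- com(moving, NULL) - cf

  spacings <- min(fixed$grid$spacing) * 2^((levels - 1):0)
  par <- par0
  for (sp in spacings) {
    f_lo <- resample(fixed, sp, "linear")
    m_lo <- resample(moving, sp, "linear")
    k_lo <- if (!is.null(mask)) resample(mask, sp, "nearest") else NULL
    sel <- if (!is.null(k_lo)) as.vector(k_lo$values > 0) else
      rep(TRUE, prod(f_lo$grid$shape))
    if (!any(sel)) next
    pts <- grid_points(f_lo$grid)[sel, , drop = FALSE]
    fv <- as.vector(f_lo$values)[sel]
    objective <- function(p) {
      tr <- params_to_affine(p, model, d, center)
      idx <- physical_to_continuous_index(m_lo$grid,
                                          apply_transform(tr, pts))
      mv <- cpp_interp(m_lo$values, idx, FALSE, 0)
      mean((fv - mv)^2)
    }
    # parameter scales: angles/log-scale/matrix entries ~0.1, translations
    # ~ one coarse voxel
    scale <- rep(0.1, np)
    scale[(np - d + 1):np] <- sp
    opt <- optim(par, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, parscale = scale,
                                reltol = 1e-9))
    par <- opt$par
  }
  tr <- params_to_affine(par, model, d, center)
  structure(list(transform = tr, model = model, requested = model,
                 fallback = FALSE, rms_residual = sqrt(opt$value),
                 labels_used = integer(0),
                 converged = opt$convergence == 0),
            class = "linear_fit")
}
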