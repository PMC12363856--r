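# Greedy compositional diffeomorphic registration.
#
# A demons-style engine stands in for a full symmetric-normalisation
# optimizer while honouring the same contract: masked metric, fluid
# (update) + elastic (total) Gaussian regularisation, capped per-iteration
# step so the accumulated field stays diffeomorphic, and a dense inverse
# maintained by fixed-point inversion.

#' Deformable registration parameters
#'
#' @param levels resolution levels (downsampling factor 2 between levels).
#' @param iters_per_level iteration budget per level, coarse to fine.
#' @param metric `"mse"` (mean-squared intensity difference) or `"lncc"`
#'   (local normalised cross-correlation).
#' @param lncc_window Gaussian window of the LNCC local statistics, voxels.
#' @param update_sigma fluid-like smoothing of each update, voxels.
#' @param total_sigma elastic-like smoothing of the accumulated field,
#'   voxels.
#' @param max_step largest per-iteration displacement, voxels; must stay
#'   below 0.5 so each incremental map is invertible.
#' @param convergence_tol relative metric change that stops a level.
#' @return list of class `deformable_params`.
#' @export
deformable_params <- function(levels = 3L, iters_per_level = c(60, 40, 20),
                              metric = c("mse", "lncc"), lncc_window = 4,
                              update_sigma = 2.0, total_sigma = 1.0,
                              max_step = 0.4, convergence_tol = 1e-5) {
  metric <- match.arg(metric)
  if (max_step >= 0.5) stop("deformable_params: max_step must be < 0.5")
  if (update_sigma < 0 || total_sigma < 0)
    stop("deformable_params: sigmas must be >= 0")
  iters_per_level <- rep_len(as.integer(iters_per_level), levels)
  structure(list(levels = as.integer(levels),
                 iters_per_level = iters_per_level, metric = metric,
                 lncc_window = lncc_window, update_sigma = update_sigma,
                 total_sigma = total_sigma, max_step = max_step,
                 convergence_tol = convergence_tol),
            class = "deformable_params")
}

smooth_field_array <- function(u, sigma_vox) {
  if (sigma_vox <= 0) return(u)
  dims <- dim(u)
  d <- dims[length(dims)]
  for (c in seq_len(d)) {
    comp <- if (d == 2) u[, , c] else u[, , , c]
    sm <- cpp_gauss_smooth(as.array(comp), rep(sigma_vox, d))
    if (d == 2) u[, , c] <- sm else u[, , , c] <- sm
  }
  u
}

# physical-space gradient of a scalar array on a grid (n x d matrix)
physical_gradient <- function(vals, grid) {
  d <- grid_dim(grid)
  Ainv <- solve(grid$direction %*% diag(grid$spacing, d))
  G <- index_gradient(as.array(vals))
  n <- prod(grid$shape)
  out <- matrix(0, n, d)
  for (j in seq_len(d))
    for (k in seq_len(d))
      out[, j] <- out[, j] + as.vector(G[[k]]) * Ainv[k, j]
  out
}

# Metric value and displacement force for one channel at the current warp.
# Returns list(value, force n x d) evaluated on `grid`, masked by `sel`.
channel_force <- function(fv, wv, grid, sel, params) {
  d <- grid_dim(grid)
  n <- prod(grid$shape)
  if (params$metric == "mse") {
    delta <- fv - wv
    value <- mean(delta[sel]^2)
    grad <- physical_gradient(array(wv, grid$shape), grid)
    c2 <- mean(grid$spacing)^2
    gn2 <- rowSums(grad^2)
    denom <- gn2 + delta^2 / c2
    coef <- ifelse(denom > 0, delta / denom, 0)
    force <- grad * coef
  } else {
    sig <- params$lncc_window / 2
    sm <- function(x) as.vector(cpp_gauss_smooth(array(x, grid$shape),
                                                 rep(sig, d)))
    fbar <- sm(fv); wbar <- sm(wv)
    fp <- fv - fbar; wp <- wv - wbar
    sfm <- sm(fp * wp); sff <- sm(fp * fp); smm <- sm(wp * wp)
    eps <- 1e-8 * mean(sff + smm)^1 + 1e-12
    cc <- sfm^2 / (sff * smm + eps)
    value <- 1 - mean(cc[sel])
    grad <- physical_gradient(array(wv, grid$shape), grid)
    coef <- 2 * sfm / (sff * smm + eps) * (fp - sfm / (smm + eps) * wp)
    force <- grad * coef
  }
  force[!sel, ] <- 0
  list(value = value, force = force)
}

# Shared greedy multi-resolution engine.
# channels: list of list(fixed = scalar_image, moving = scalar_image,
#                        weight = w); all fixed on one grid.
# init: composite/affine transform applied after the optimised field, i.e.
#       the total map is x -> init(x + u(x)).
greedy_engine <- function(channels, init, fixed_grid, fixed_mask, params) {
  d <- grid_dim(fixed_grid)
  levels <- params$levels
  spacings <- lapply((levels - 1):0,
                     function(k) fixed_grid$spacing * 2^k)
  u <- NULL
  trace <- list()
  for (lev in seq_len(levels)) {
    sp <- spacings[[lev]]
    f_lo <- lapply(channels, function(ch) resample(ch$fixed, sp, "linear"))
    grid_lo <- f_lo[[1]]$grid
    mask_lo <- if (!is.null(fixed_mask))
      resample(fixed_mask, sp, "nearest") else NULL
    sel <- if (!is.null(mask_lo)) as.vector(mask_lo$values > 0) else
      rep(TRUE, prod(grid_lo$shape))
    if (!any(sel)) stop("deformable: empty mask at level ", lev)
    pts <- grid_points(grid_lo)
    n <- nrow(pts)

    if (is.null(u)) {
      u <- matrix(0, n, d)
    } else {
      prev <- displacement_field(grid_prev, array(u, c(grid_prev$shape, d)))
      u <- vapply(seq_len(d),
                  function(c) sample_field_component(prev, c, pts),
                  numeric(n))
    }

    fvals <- lapply(f_lo, function(img) as.vector(img$values))
    weights <- vapply(channels, function(ch) ch$weight %||% 1, numeric(1))
    step_cap <- params$max_step * min(grid_lo$spacing)
    step_scale <- 1
    prev_metric <- Inf

    for (it in seq_len(params$iters_per_level[lev])) {
      q <- pts + u
      mapped <- apply_transform(init, q)
      value <- 0
      force <- matrix(0, n, d)
      for (ci in seq_along(channels)) {
        mv_img <- channels[[ci]]$moving
        idx <- physical_to_continuous_index(mv_img$grid, mapped)
        wv <- cpp_interp(mv_img$values, idx, FALSE, 0)
        cf <- channel_force(fvals[[ci]], wv, grid_lo, sel, params)
        value <- value + weights[ci] * cf$value
        force <- force + weights[ci] * cf$force
      }
      accepted <- !(it > 1 && value > prev_metric)
      trace[[length(trace) + 1L]] <- c(level = lev, iter = it,
                                       metric = value,
                                       accepted = as.numeric(accepted))
      rel <- (prev_metric - value) / max(abs(prev_metric), 1e-30)
      if (it > 1 && is.finite(prev_metric) &&
          rel < params$convergence_tol && rel >= 0) break
      if (!accepted) {
        # step too aggressive: revert and halve
        u <- u_prev
        step_scale <- step_scale / 2
        if (step_scale < 0.05) break
        next
      }
      prev_metric <- value
      u_prev <- u

      du <- array(force, c(grid_lo$shape, d))
      du <- smooth_field_array(du, params$update_sigma)
      dm <- matrix(du, n, d)
      mx <- max(sqrt(rowSums(dm^2)))
      if (mx > 0) dm <- dm * (step_scale * step_cap / mx)
      # compose: u_new(x) = du(x) + u(x + du(x))
      cur <- displacement_field(grid_lo, array(u, c(grid_lo$shape, d)))
      qq <- pts + dm
      u_at <- vapply(seq_len(d),
                     function(c) sample_field_component(cur, c, qq),
                     numeric(n))
      u <- dm + u_at
      u <- matrix(smooth_field_array(array(u, c(grid_lo$shape, d)),
                                     params$total_sigma), n, d)
    }
    grid_prev <- grid_lo
  }

  fwd <- displacement_field(fixed_grid, array(u, c(fixed_grid$shape, d)))
  # diffeomorphism safeguard: smooth harder if the accumulated field folds
  for (try in 1:3) {
    jac <- jacobian_image(fwd, fixed_grid, log = FALSE)
    if (min(jac$values[interior_mask(fixed_grid)]) > 0) break
    fwd <- displacement_field(
      fixed_grid, smooth_field_array(fwd$vectors, 1.0))
  }
  inv <- invert_field(fwd, tol = 0.02 * min(fixed_grid$spacing),
                      max_iter = 100L)
  tr <- as.data.frame(do.call(rbind, trace))
  list(forward = fwd, inverse = inv, trace = tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deformable intensity registration
#'
#' Greedy multi-resolution diffeomorphic registration of `moving` to `fixed`
#' driven by an intensity similarity metric, restricted to `fixed_mask`,
#' initialised by `init` (typically the stage-1 linear transform). The
#' optimised displacement field `u` acts on fixed-space points before
#' `init`: the total forward map is `x -> init(x + u(x))`.
#'
#' @param fixed,moving `scalar_image`s.
#' @param init transform mapping fixed space into moving space (default
#'   identity).
#' @param fixed_mask optional `label_image` on the fixed grid.
#' @param params a [deformable_params()].
#' @return List with `forward` and `inverse` `displacement_field`s on the
#'   fixed grid and a per-iteration metric `trace` (data.frame).
#' @export
deformable_register <- function(fixed, moving,
                                init = identity_transform(
                                  grid_dim(fixed$grid)),
                                fixed_mask = NULL,
                                params = deformable_params()) {
  channels <- list(list(fixed = fixed, moving = moving, weight = 1))
  greedy_engine(channels, init, fixed$grid, fixed_mask, params)
}

#' Label metric parameters
#'
#' Controls how label maps are rendered as real-valued channels for the
#' label-similarity refinement stage.
#'
#' @param representation `"smoothed_indicator"` (Gaussian-smoothed binary
#'   indicator per label) or `"signed_distance"`.
#' @param sigma smoothing of the indicator, voxels.
#' @param weights named numeric vector of per-label weights (default 1 for
#'   every shared label).
#' @return list of class `label_metric_params`.
#' @export
label_metric_params <- function(representation = c("smoothed_indicator",
                                                   "signed_distance"),
                                sigma = 2, weights = NULL) {
  representation <- match.arg(representation)
  if (!is.null(weights) && any(weights < 0))
    stop("label_metric_params: weights must be >= 0")
  structure(list(representation = representation, sigma = sigma,
                 weights = weights),
            class = "label_metric_params")
}

# real-valued rendering of one label
label_channel <- function(labels, lab, label_params) {
  grid <- labels$grid
  ind <- array(as.numeric(labels$values == lab), grid$shape)
  if (label_params$representation == "smoothed_indicator") {
    v <- cpp_gauss_smooth(ind, rep(label_params$sigma, grid_dim(grid)))
  } else {
    # signed distance approximated by smoothed indicator remapped around
    # the 0.5 level set (monotone surrogate adequate for a gradient force)
    sm <- cpp_gauss_smooth(ind, rep(label_params$sigma, grid_dim(grid)))
    v <- sm - 0.5
  }
  scalar_image(grid, as.array(v))
}

#' Label-similarity refinement
#'
#' Runs the same greedy engine with one real-valued channel per shared
#' label (see [label_metric_params()]), with per-label weights, using
#' mean-squared channel difference as the metric. Typically initialised by
#' the composite of stages 1-2.
#'
#' @param fixed_labels,moving_labels `label_image`s sharing at least one
#'   label.
#' @param init transform mapping fixed space into moving space.
#' @param fixed_mask optional mask on the fixed grid.
#' @param label_params a [label_metric_params()].
#' @param params a [deformable_params()]; metric is forced to `"mse"` on
#'   the rendered channels.
#' @return As [deformable_register()].
#' @export
label_metric_refine <- function(fixed_labels, moving_labels,
                                init = identity_transform(
                                  grid_dim(fixed_labels$grid)),
                                fixed_mask = NULL,
                                label_params = label_metric_params(),
                                params = deformable_params()) {
  shared <- intersect(label_set(fixed_labels), label_set(moving_labels))
  if (length(shared) == 0) stop("label_metric_refine: no shared labels")
  w <- rep(1, length(shared)); names(w) <- as.character(shared)
  if (!is.null(label_params$weights)) {
    m <- match(names(label_params$weights), names(w))
    w[m[!is.na(m)]] <- label_params$weights[!is.na(m)]
  }
  keep <- w > 0
  shared <- shared[keep]; w <- w[keep]
  if (length(shared) == 0)
    stop("label_metric_refine: all label weights zero")
  params$metric <- "mse"
  channels <- lapply(seq_along(shared), function(i) {
    list(fixed = label_channel(fixed_labels, shared[i], label_params),
         moving = label_channel(moving_labels, shared[i], label_params),
         weight = unname(w[i]))
  })
  greedy_engine(channels, init, fixed_labels$grid, fixed_mask, params)
}
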