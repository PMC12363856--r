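# Orchestration of the two registration arms and template construction.
#
# Direction convention (stated once, used everywhere): the *forward*
# composite maps fixed/template-space points into moving/subject space; it
# is the transform used to pull subject values onto the template grid and
# the transform whose Jacobian is analysed in tensor-based morphometry.
# The *inverse* composite maps subject-space points back to template space
# and feeds the deformation PCA.

#' Pipeline options
#'
#' @param arm `"label_informed"` (centroid-based linear initialisation,
#'   optional label refinement) or `"intensity_only"` (intensity-driven
#'   linear initialisation).
#' @param linear_model model for stage 1 (see
#'   [fit_linear_from_centroids()]).
#' @param deformable a [deformable_params()].
#' @param label_refine logical: run the optional stage-3 label-similarity
#'   refinement (label-informed arm only).
#' @param label_params a [label_metric_params()] for stage 3.
#' @return list of class `pipeline_options`.
#' @export
pipeline_options <- function(arm = c("label_informed", "intensity_only"),
                             linear_model = "affine",
                             deformable = deformable_params(),
                             label_refine = FALSE,
                             label_params = label_metric_params()) {
  arm <- match.arg(arm)
  structure(list(arm = arm, linear_model = linear_model,
                 deformable = deformable, label_refine = label_refine,
                 label_params = label_params),
            class = "pipeline_options")
}

make_registration_result <- function(forward_list, inverse_list, fixed_int,
                                     moving_int, moving_labels, reports) {
  forward <- composite_transform(forward_list)
  inverse <- composite_transform(inverse_list)
  warped_intensity <- warp_image(moving_int, forward, fixed_int$grid,
                                 "linear")
  warped_labels <- if (!is.null(moving_labels))
    warp_image(moving_labels, forward, fixed_int$grid, "nearest") else NULL
  structure(list(forward = forward, inverse = inverse,
                 warped_intensity = warped_intensity,
                 warped_labels = warped_labels, reports = reports),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("registration_result:", length(x$forward$transforms),
      "forward stage(s);",
      if (!is.null(x$reports$linear)) paste0("linear model ",
                                             x$reports$linear$model), "\n")
  invisible(x)
}

#' Label-informed registration of a subject to a template
#'
#' Stage 1 fits a linear transform from the centers of mass of corresponding
#' label maps (or uses `init_transform` if supplied); stage 2 runs masked
#' deformable registration of the intensity images initialised by stage 1;
#' stage 3 (optional) refines with a label-similarity metric. The forward
#' composite is `[linear, field]` (field applied first to fixed-space
#' points), the inverse `[inverse field, inverse linear]`.
#'
#' @param fixed_int,moving_int `scalar_image`s (template, subject).
#' @param fixed_labels,moving_labels `label_image`s with shared labels.
#' @param mask optional fixed-space mask limiting the metric.
#' @param options a [pipeline_options()] with `arm = "label_informed"`.
#' @param init_transform optional user-supplied stage-1 transform
#'   (fixed -> moving) overriding the centroid fit.
#' @param label_weights optional named per-label weights for the centroid
#'   fit.
#' @return A `registration_result`.
#' @export
label_image_registration <- function(fixed_int, fixed_labels, moving_int,
                                     moving_labels, mask = NULL,
                                     options = pipeline_options(
                                       "label_informed"),
                                     init_transform = NULL,
                                     label_weights = NULL) {
  if (is.null(fixed_labels) || is.null(moving_labels))
    stop("label_image_registration: label images required on both sides")
  reports <- list()
  if (is.null(init_transform)) {
    fit <- fit_linear_from_centroids(
      label_centroids(fixed_labels, label_weights),
      label_centroids(moving_labels, label_weights),
      model = options$linear_model)
    linear <- fit$transform
    reports$linear <- fit
  } else {
    linear <- init_transform
    reports$linear <- list(transform = linear, model = "user")
  }
  stage2 <- deformable_register(fixed_int, moving_int, init = linear,
                                fixed_mask = mask,
                                params = options$deformable)
  reports$deformable_trace <- stage2$trace
  forward_list <- list(linear, stage2$forward)
  inverse_list <- list(stage2$inverse, invert_affine(linear))
  if (isTRUE(options$label_refine)) {
    init23 <- composite_transform(forward_list)
    stage3 <- label_metric_refine(fixed_labels, moving_labels,
                                  init = init23, fixed_mask = mask,
                                  label_params = options$label_params,
                                  params = options$deformable)
    reports$refine_trace <- stage3$trace
    forward_list <- list(linear, stage2$forward, stage3$forward)
    # total map: linear(F2(F3(x))); inverse: F3^-1(F2^-1(linear^-1(y)))
    inverse_list <- list(stage3$inverse, stage2$inverse,
                         invert_affine(linear))
  }
  make_registration_result(forward_list, inverse_list, fixed_int,
                           moving_int, moving_labels, reports)
}

#' Intensity-only registration of a subject to a template
#'
#' Stage 1 is a multi-resolution intensity-driven linear registration;
#' stage 2 the same masked deformable registration as the label-informed
#' arm. No label refinement stage.
#'
#' @inheritParams label_image_registration
#' @param moving_labels optional labels carried through for warping only.
#' @return A `registration_result`.
#' @export
intensity_only_registration <- function(fixed_int, moving_int, mask = NULL,
                                        options = pipeline_options(
                                          "intensity_only"),
                                        moving_labels = NULL) {
  fit <- intensity_linear_register(fixed_int, moving_int, mask = mask,
                                   model = options$linear_model)
  linear <- fit$transform
  stage2 <- deformable_register(fixed_int, moving_int, init = linear,
                                fixed_mask = mask,
                                params = options$deformable)
  make_registration_result(
    list(linear, stage2$forward),
    list(stage2$inverse, invert_affine(linear)),
    fixed_int, moving_int, moving_labels,
    list(linear = fit, deformable_trace = stage2$trace))
}

#' Collapse a registration result to a dense field
#'
#' @param result a `registration_result`.
#' @param which `"forward"` or `"inverse"`.
#' @param reference grid on which to sample the composed map.
#' @return A `displacement_field`.
#' @export
combined_field <- function(result, which = c("forward", "inverse"),
                           reference) {
  which <- match.arg(which)
  compose_to_field(result[[which]], reference)
}

#' Mean endpoint error between two transforms
#'
#' Mean Euclidean distance (mm) between the images of the masked fixed-grid
#' voxel centers under the two transforms; the standard recovery score
#' against a known ground-truth deformation.
#'
#' @param transform_a,transform_b transforms on the same fixed space.
#' @param grid fixed-space [image_grid()].
#' @param mask optional `label_image`; error averaged over mask > 0.
#' @return mean endpoint error in mm.
#' @export
endpoint_error <- function(transform_a, transform_b, grid, mask = NULL) {
  pts <- grid_points(grid)
  if (!is.null(mask)) pts <- pts[as.vector(mask$values > 0), , drop = FALSE]
  pa <- apply_transform(transform_a, pts)
  pb <- apply_transform(transform_b, pts)
  mean(sqrt(rowSums((pa - pb)^2)))
}

#' Dice overlap per label
#'
#' @param a,b `label_image`s on the same grid.
#' @param labels labels to score (default: union of nonzero labels).
#' @return named numeric vector of Dice coefficients.
#' @export
label_dice <- function(a, b, labels = union(label_set(a), label_set(b))) {
  va <- as.vector(a$values); vb <- as.vector(b$values)
  out <- vapply(labels, function(l) {
    ia <- va == l; ib <- vb == l
    s <- sum(ia) + sum(ib)
    if (s == 0) return(NA_real_)
    2 * sum(ia & ib) / s
  }, numeric(1))
  names(out) <- as.character(labels)
  out
}

# unsharp mask: img + amount * (img - gaussian(img, sigma))
sharpen_image <- function(img, sigma = 1, amount = 0.5) {
  d <- grid_dim(img$grid)
  blur <- cpp_gauss_smooth(img$values, rep(sigma, d))
  scalar_image(img$grid, img$values + amount * (img$values - blur))
}

#' Iterative template construction
#'
#' Builds an average (template) image from a cohort: the initial template is
#' the voxelwise mean of the (assumed rigidly pre-aligned) subjects; each
#' iteration registers every subject to the current template, averages the
#' warped intensities, and applies a mild unsharp mask (sigma 1 voxel,
#' amount 0.5) to counteract the blurring of averaging.
#'
#' @param subjects list of `scalar_image`s on a common grid.
#' @param iterations number of refinement iterations (default 3).
#' @param options a [pipeline_options()]; the intensity-only arm is used
#'   unless `labels` are supplied for every subject.
#' @param labels optional list of `label_image`s (enables the
#'   label-informed arm).
#' @param template_labels labels of the evolving template (required when
#'   `labels` given; taken from the first subject initially).
#' @param mask optional template-space mask.
#' @return List with `template` (`scalar_image`) and `history` (mean
#'   absolute change of the template per iteration).
#' @export
build_template <- function(subjects, iterations = 3L,
                           options = pipeline_options("intensity_only"),
                           labels = NULL, template_labels = NULL,
                           mask = NULL) {
  if (length(subjects) < 2) stop("build_template: need at least 2 subjects")
  grid <- subjects[[1]]$grid
  for (s in subjects)
    if (!grid_equal(s$grid, grid))
      stop("build_template: subjects must share a grid")
  avg <- Reduce(`+`, lapply(subjects, function(s) s$values)) /
    length(subjects)
  template <- scalar_image(grid, avg)
  if (!is.null(labels) && is.null(template_labels))
    template_labels <- labels[[1]]
  history <- numeric(0)
  for (it in seq_len(iterations)) {
    warped <- vector("list", length(subjects))
    ok <- logical(length(subjects))
    for (i in seq_along(subjects)) {
      res <- tryCatch({
        if (!is.null(labels))
          label_image_registration(template, template_labels,
                                   subjects[[i]], labels[[i]],
                                   mask = mask, options = options)
        else
          intensity_only_registration(template, subjects[[i]],
                                      mask = mask, options = options)
      }, error = function(e) {
        warning("build_template: subject ", i, " skipped (",
                conditionMessage(e), ")")
        NULL
      })
      if (!is.null(res)) {
        warped[[i]] <- res$warped_intensity$values
        ok[i] <- TRUE
      }
    }
    if (sum(ok) < 2)
      stop("build_template: fewer than 2 subjects registered")
    newt <- Reduce(`+`, warped[ok]) / sum(ok)
    newt <- sharpen_image(scalar_image(grid, newt))
    history <- c(history, mean(abs(newt$values - template$values)))
    template <- newt
  }
  list(template = template, history = history)
}
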