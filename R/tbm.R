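# Tensor-based morphometry: voxel-wise group comparison of log-Jacobian
# images with Benjamini-Hochberg FDR control.

#' Voxel-wise two-group regression of log-Jacobian images
#'
#' At every voxel inside the analysis mask, ordinary least squares of log J
#' on an intercept plus a group indicator; the t statistic of the group
#' coefficient with `nA + nB - 2` degrees of freedom is numerically
#' identical to the pooled two-sample t-test. The group-difference map
#' `beta` is mean(B) - mean(A): with A the reference (wildtype-like) group,
#' negative beta means local volume reduction in group B.
#'
#' Voxels where any subject's log J is non-finite are dropped from the
#' analysis (counted in `n_nonfinite`); voxels with zero residual variance
#' get p = 0 when the means differ and p = 1 when they agree, and are
#' counted in `n_constant`.
#'
#' @param jacs_a,jacs_b lists of `jacobian_image`s (or `scalar_image`s) on
#'   one grid; at least two per group.
#' @param mask `label_image` defining the analysis region (default: whole
#'   grid).
#' @param alpha FDR level used for the significance mask.
#' @return List of class `tbm_result` with `beta`, `t`, `p`, `q` (scalar
#'   images; q = 1 outside the analysed voxels), `sig_mask` (`label_image`),
#'   `n_sig`, `n_voxels`, `jac_range` (range of per-group mean log J over
#'   analysed voxels), `n_constant`, `n_nonfinite`, `alpha`.
#' @export
voxelwise_group_regression <- function(jacs_a, jacs_b, mask = NULL,
                                       alpha = 0.05) {
  na <- length(jacs_a); nb <- length(jacs_b)
  if (na < 2 || nb < 2)
    stop("voxelwise_group_regression: need >= 2 subjects per group")
  grid <- jacs_a[[1]]$grid
  for (j in c(jacs_a, jacs_b))
    if (!grid_equal(j$grid, grid))
      stop("voxelwise_group_regression: grids differ")
  nvox <- prod(grid$shape)
  inmask <- if (!is.null(mask)) as.vector(mask$values > 0) else
    rep(TRUE, nvox)
  A <- vapply(jacs_a, function(j) as.vector(j$values), numeric(nvox))
  B <- vapply(jacs_b, function(j) as.vector(j$values), numeric(nvox))
  finite <- rowSums(!is.finite(A)) + rowSums(!is.finite(B)) == 0
  analyse <- inmask & finite
  n_nonfinite <- sum(inmask & !finite)

  ma <- rowMeans(A); mb <- rowMeans(B)
  beta <- mb - ma
  ssa <- rowSums((A - ma)^2); ssb <- rowSums((B - mb)^2)
  df <- na + nb - 2
  s2 <- (ssa + ssb) / df
  se <- sqrt(s2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, beta / se, 0)
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  const <- analyse & se == 0
  p[const] <- ifelse(abs(beta[const]) > 0, 0, 1)
  tstat[const & abs(beta) > 0] <- Inf * sign(beta[const & abs(beta) > 0])

  q <- rep(1, nvox)
  sig <- rep(FALSE, nvox)
  if (any(analyse)) {
    bh <- bh_fdr(p[analyse], alpha = alpha)
    q[analyse] <- bh$q
    sig[analyse] <- bh$significant
  }
  as_img <- function(v, cls = "scalar_image") {
    v[!analyse] <- if (identical(cls, "p")) 1 else v[!analyse]
    dim(v) <- grid$shape
    structure(list(grid = grid, values = v),
              class = c("scalar_image", "spatial_image"))
  }
  beta_img <- beta; beta_img[!analyse] <- 0
  t_img <- tstat; t_img[!analyse] <- 0
  p_img <- p; p_img[!analyse] <- 1
  jr <- range(c(ma[analyse], mb[analyse]))
  structure(list(beta = as_img(beta_img), t = as_img(t_img),
                 p = as_img(p_img), q = as_img(q),
                 sig_mask = label_image(grid,
                                        array(as.integer(sig),
                                              grid$shape)),
                 n_sig = sum(sig), n_voxels = sum(analyse),
                 jac_range = jr, n_constant = sum(const),
                 n_nonfinite = n_nonfinite, alpha = alpha),
            class = "tbm_result")
}

#' @export
print.tbm_result <- function(x, ...) {
  cat("tbm_result:", x$n_voxels, "voxels analysed,", x$n_sig,
      "significant at FDR", x$alpha, "\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1; the significant set
#' is `q < alpha`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return List with `q` (adjusted values, input order) and `significant`
#'   (logical).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_fdr: p outside [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, significant = q < alpha)
}

#' Significance heatmap of a TBM result
#'
#' The group-difference `beta` (mean log J of group B minus group A) at
#' voxels significant at the FDR level, 0 elsewhere, clipped to `clip`:
#' positive values mark local volume expansion in group B, negative local
#' volume reduction.
#'
#' @param result a `tbm_result`.
#' @param clip two-sided display clip, default `c(-1, 1)`.
#' @return A `scalar_image`.
#' @export
tbm_heatmap <- function(result, clip = c(-1, 1)) {
  v <- result$beta$values
  v[result$sig_mask$values == 0L] <- 0
  v <- pmin(pmax(v, clip[1]), clip[2])
  dim(v) <- result$beta$grid$shape
  scalar_image(result$beta$grid, v)
}
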