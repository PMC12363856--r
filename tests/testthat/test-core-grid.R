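# Grid model, warping, composition, inversion, Jacobians.

test_that("index_to_physical applies the voxel-center affine map", {
  g <- image_grid(c(8, 8, 8))
  expect_equal(index_to_physical(g, c(2, 3, 4)), c(2, 3, 4))
  expect_equal(index_to_physical(g, c(0, 0, 0)), g$origin)

  g2 <- image_grid(c(32, 16, 16), spacing = 0.06, origin = c(1, 1, 1))
  expect_equal(index_to_physical(g2, c(10, 0, 0)), c(1.6, 1, 1))
  expect_error(index_to_physical(g2, c(32, 0, 0)), "out of range")

  # with a non-identity direction the map is origin + D %*% (s * i)
  R <- rbind(c(0, -1), c(1, 0))
  g3 <- image_grid(c(5, 5), spacing = c(2, 3), origin = c(1, -1),
                   direction = R)
  expect_equal(index_to_physical(g3, c(1, 1)),
               c(1, -1) + drop(R %*% c(2, 3)))
})

test_that("grid invariants are enforced", {
  expect_error(image_grid(c(8, 8), spacing = 0), "positive")
  expect_error(image_grid(c(8, 8), direction = matrix(1, 2, 2)),
               "orthonormal")
  expect_error(image_grid(8), "dimensionality")
})

test_that("resample preserves extent and constants", {
  g <- image_grid(c(100, 10, 10), spacing = 0.018)
  img <- scalar_image(g, array(7, g$shape))
  out <- resample(img, 0.060)
  expect_identical(out$grid$shape[1], 30L)   # ceil(100 * 18 / 60)
  expect_equal(max(abs(out$values - 7)), 0, tolerance = 1e-12)
  expect_equal(out$grid$origin, g$origin)

  lab <- label_image(g, array(sample(0:3, prod(g$shape), TRUE), g$shape))
  expect_error(resample(lab, 0.06, "linear"), "nearest")
  lr <- resample(lab, 0.05)
  expect_true(all(label_set(lr) %in% label_set(lab)))
})

test_that("warp_image is exact under identity and pure voxel translations", {
  img <- smooth_image2()
  g <- img$grid
  w_lin <- warp_image(img, identity_transform(2), g, "linear")
  w_nn <- warp_image(img, identity_transform(2), g, "nearest")
  expect_lt(max(abs(w_lin$values - img$values)), 1e-12)
  expect_identical(w_nn$values, img$values)

  # translation by k whole voxels shifts the array by -k in index space
  k <- c(3, -2)
  tr <- translation_transform(k * g$spacing)
  w <- warp_image(img, tr, g, "linear")
  n <- g$shape
  inner_x <- 5:(n[1] - 5); inner_y <- 5:(n[2] - 5)
  expect_equal(w$values[inner_x, inner_y],
               img$values[inner_x + k[1], inner_y + k[2]],
               tolerance = 1e-12)
})

test_that("warping a label image cannot invent labels", {
  g <- tiny_grid2()
  set.seed(3)
  lab <- label_image(g, array(sample(c(0L, 2L, 5L), prod(g$shape), TRUE),
                              g$shape))
  fld <- smooth_field3(g, 0.3, seed = 4)
  w <- warp_image(lab, fld, g, "nearest")
  expect_true(all(w$values %in% c(0L, 2L, 5L)))
  expect_error(warp_image(lab, fld, g, "linear"), "nearest")
})

test_that("warp_image is exact on constant images regardless of transform", {
  g <- tiny_grid2()
  img <- scalar_image(g, array(3.5, g$shape))
  fld <- smooth_field3(g, 0.4, seed = 9)
  # restrict to reference points that stay inside the domain: interior
  w <- warp_image(img, fld, g, "linear")
  inner <- labelmorph:::interior_mask(g, margin = 3)
  expect_true(all(abs(w$values[inner] - 3.5) < 1e-12))
})

test_that("compose_to_field matches identities and a pointwise oracle", {
  g <- image_grid(c(10, 10, 10), 0.7)
  z <- compose_to_field(identity_transform(3), g)
  expect_true(all(z$vectors == 0))

  t1 <- translation_transform(c(1, 0, -2))
  t2 <- translation_transform(c(0.5, 0.25, 0))
  f <- compose_to_field(list(t1, t2), g)
  expect_equal(range(f$vectors[, , , 1]), c(1.5, 1.5))
  expect_equal(range(f$vectors[, , , 2]), c(0.25, 0.25))
  expect_equal(range(f$vectors[, , , 3]), c(-2, -2))

  # [affine A, field F] against brute-force per-point evaluation
  A <- affine_transform(diag(3) * 1.05, translation = c(0.2, -0.1, 0),
                        center = c(3, 3, 3))
  F <- smooth_field3(g, 0.2, seed = 6)
  comp <- compose_to_field(list(A, F), g)
  set.seed(7)
  idx <- sample(prod(g$shape), 50)
  pts <- labelmorph:::grid_points(g)[idx, ]
  oracle <- apply_transform(A, apply_transform(F, pts))
  got <- pts + matrix(comp$vectors, prod(g$shape), 3)[idx, ]
  expect_lt(max(abs(got - oracle)), 1e-6)
})

test_that("invert_field inverts translations exactly and smooth fields to tol", {
  g <- image_grid(c(14, 14, 14), 0.5)
  z <- invert_field(zero_field(g))
  expect_true(all(z$vectors == 0))

  t <- c(0.6, -0.4, 0.2)
  ft <- compose_to_field(translation_transform(t), g)
  inv <- invert_field(ft)
  interior <- labelmorph:::interior_mask(g, 2)
  m <- matrix(inv$vectors, prod(g$shape), 3)
  expect_lt(max(abs(sweep(m[as.vector(interior), ], 2, -t, "-"))), 1e-6)

  # smooth random diffeomorphic field: composition residual <= 0.1 voxel
  fr <- smooth_field3(g, 0.3, seed = 3)
  iv <- invert_field(fr, max_iter = 100)
  comp <- compose_to_field(list(fr, iv), g)
  resid <- sqrt(rowSums(matrix(comp$vectors, prod(g$shape), 3)^2))
  expect_lt(max(resid[as.vector(interior)]) / min(g$spacing), 0.1)
  expect_true(attr(iv, "converged"))
})

test_that("jacobian_image reproduces closed forms", {
  g <- image_grid(c(12, 12, 12), 0.25)
  j_id <- jacobian_image(identity_transform(3), g)
  expect_true(all(j_id$values == 0))
  expect_identical(attr(j_id, "n_folded"), 0L)

  j_s <- jacobian_image(affine_transform(1.2 * diag(3)), g)
  expect_equal(max(abs(j_s$values - 3 * log(1.2))), 0, tolerance = 1e-10)
  j_raw <- jacobian_image(affine_transform(1.2 * diag(3)), g, log = FALSE)
  expect_equal(mean(j_raw$values), 1.728, tolerance = 1e-10)

  # analytic shear field u = (alpha * x1, 0, 0)
  alpha <- 0.1
  pts <- labelmorph:::grid_points(g)
  u <- array(0, c(g$shape, 3))
  u[, , , 1] <- array(alpha * pts[, 1], g$shape)
  j_f <- jacobian_image(displacement_field(g, u), g)
  expect_equal(max(abs(j_f$values - log(1 + alpha))), 0, tolerance = 1e-9)
})

test_that("jacobian of any affine is constant at log|det| over the interior", {
  g <- image_grid(c(10, 12, 9), c(0.3, 0.25, 0.4))
  set.seed(8)
  for (rep in 1:3) {
    M <- diag(3) + matrix(rnorm(9, 0, 0.15), 3, 3)
    j <- jacobian_image(affine_transform(M, translation = rnorm(3)), g)
    interior <- labelmorph:::interior_mask(g)
    expect_lt(max(abs(j$values[interior] - log(abs(det(M))))), 1e-6)
  }
})

test_that("folding is detected and flagged with -Inf log J", {
  g <- image_grid(c(10, 10), 1)
  pts <- labelmorph:::grid_points(g)
  u <- array(0, c(g$shape, 2))
  u[, , 1] <- array(-2 * pts[, 1], g$shape)   # x -> -x, J < 0
  j <- jacobian_image(displacement_field(g, u), g)
  expect_true(attr(j, "n_folded") > 0)
  expect_true(all(j$values[is.finite(j$values)] <= 0) ||
                any(is.infinite(j$values)))
})

test_that("warped-region volume matches the Jacobian integral (conservation)", {
  g <- image_grid(c(24, 24, 24), 0.25)
  fld <- smooth_field3(g, 0.15, seed = 12)
  ctr <- index_to_physical(g, (g$shape - 1) / 2)
  ball <- labelmorph:::ellipsoid_mask(g, ctr, rep(1.4, 3))
  lab <- label_image(g, array(as.integer(ball), g$shape))
  # region transported by the map T = x + u: warp by the inverse
  inv <- invert_field(fld, max_iter = 100)
  w <- warp_image(lab, inv, g, "nearest")
  vol_warped <- sum(w$values) * labelmorph:::grid_voxel_volume(g)
  jac <- jacobian_image(fld, g, log = FALSE)
  vol_pred <- sum(jac$values[ball]) * labelmorph:::grid_voxel_volume(g)
  expect_lt(abs(vol_warped - vol_pred) / vol_pred, 0.05)
})
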