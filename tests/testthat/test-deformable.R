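# Greedy diffeomorphic engine: identity behaviour, recovery, consistency.

test_that("registering an image to itself stays at identity", {
  img <- smooth_image2(tiny_grid2(32))
  r <- deformable_register(img, img,
                           params = deformable_params(
                             levels = 2, iters_per_level = c(20, 10)))
  expect_lt(max(abs(r$forward$vectors)) / min(img$grid$spacing), 0.1)
})

test_that("a known smooth warp is recovered and fwd/inv are consistent", {
  tpl <- small_phantom()
  g <- tpl$intensity$grid
  pts <- labelmorph:::grid_points(g)
  ctr <- index_to_physical(g, (g$shape - 1) / 2)
  # Gaussian bump, 2.5-voxel peak
  u <- array(0, c(g$shape, 3))
  u[, , , 1] <- array(2.5 * g$spacing[1] *
                        exp(-rowSums(sweep(pts, 2, ctr, "-")^2) /
                              (2 * 0.8^2)), g$shape)
  truth <- displacement_field(g, u)
  moving <- warp_image(labelmorph:::clean_template_intensity(tpl),
                       invert_field(truth, max_iter = 100), g, "linear")
  r <- deformable_register(tpl$intensity, moving, fixed_mask = tpl$mask,
                           params = deformable_params())
  epe <- endpoint_error(composite_transform(list(r$forward)),
                        composite_transform(list(truth)), g, tpl$mask)
  expect_lt(epe / min(g$spacing), 0.5)

  # forward o inverse within 0.1 voxel inside the body; diffeomorphic
  comp <- compose_to_field(list(r$forward, r$inverse), g)
  resid <- sqrt(rowSums(matrix(comp$vectors, prod(g$shape), 3)^2))
  expect_lt(max(resid[tpl$mask$values > 0]) / min(g$spacing), 0.1)
  jac <- jacobian_image(r$forward, g, log = FALSE)
  expect_gt(min(jac$values[labelmorph:::interior_mask(g)]), 0)

  # metric non-increasing over accepted iterations at the finest level
  tr <- r$trace[r$trace$level == max(r$trace$level) &
                  r$trace$accepted == 1, ]
  expect_true(all(diff(tr$metric) <= 1e-12))

  # deterministic: same inputs, same output
  r2 <- deformable_register(tpl$intensity, moving, fixed_mask = tpl$mask,
                            params = deformable_params())
  expect_identical(r$forward$vectors, r2$forward$vectors)
})

test_that("lncc metric also recovers a translation under intensity scaling", {
  img <- smooth_image2(tiny_grid2(32))
  g <- img$grid
  t_true <- c(1.2, -0.8) * g$spacing
  mv <- warp_image(img, invert_affine(translation_transform(t_true)), g,
                   "linear")
  # affine intensity distortion: lncc is invariant, mse is not
  mv <- scalar_image(g, 2.5 * mv$values + 30)
  r <- deformable_register(img, mv,
                           params = deformable_params(
                             levels = 2, iters_per_level = c(40, 30),
                             metric = "lncc"))
  inner <- as.vector(labelmorph:::interior_mask(g, 8))
  um <- matrix(r$forward$vectors, prod(g$shape), 2)[inner, ]
  err <- sqrt(rowSums(sweep(um, 2, t_true, "-")^2))
  expect_lt(mean(err) / min(g$spacing), 0.5)
})

test_that("label refinement tracks a translated sphere label", {
  g <- image_grid(c(32, 32, 32), 0.12)
  ctr <- index_to_physical(g, (g$shape - 1) / 2)
  sph <- labelmorph:::ellipsoid_mask(g, ctr, rep(0.7, 3))
  fixed_lab <- label_image(g, array(as.integer(sph), g$shape))
  t_true <- c(2, 0, 0) * g$spacing
  moving_lab <- warp_image(fixed_lab,
                           invert_affine(translation_transform(t_true)),
                           g, "nearest")
  # identical labels: no motion
  r0 <- label_metric_refine(fixed_lab, fixed_lab,
                            params = deformable_params(
                              levels = 2, iters_per_level = c(15, 10)))
  expect_lt(max(abs(r0$forward$vectors)) / min(g$spacing), 0.1)

  r <- label_metric_refine(fixed_lab, moving_lab,
                           params = deformable_params(
                             levels = 2, iters_per_level = c(40, 30)))
  # recovered centroid displacement of the label within 0.3 voxel
  warped <- warp_image(moving_lab, r$forward, g, "nearest")
  c_fixed <- label_centroids(fixed_lab)
  c_warped <- label_centroids(warped)
  shift <- unlist(c_warped[1, c("c1", "c2", "c3")]) -
    unlist(c_fixed[1, c("c1", "c2", "c3")])
  expect_lt(sqrt(sum(shift^2)) / min(g$spacing), 0.3)
  expect_error(label_metric_refine(
    fixed_lab, label_image(g, array(0L, g$shape)) ), "no shared")
})

test_that("A->B and B->A registrations approximately invert each other", {
  tpl <- small_phantom()
  g <- tpl$intensity$grid
  s <- make_subject(tpl, subject_spec(0, numeric(), elastic_sd = 0.02,
                                      seed = 31))
  p <- deformable_params()
  r_ab <- deformable_register(tpl$intensity, s$intensity,
                              fixed_mask = tpl$mask, params = p)
  r_ba <- deformable_register(s$intensity, tpl$intensity,
                              fixed_mask = s$mask, params = p)
  comp <- compose_to_field(list(r_ab$forward, r_ba$forward), g)
  resid <- sqrt(rowSums(matrix(comp$vectors, prod(g$shape), 3)^2))
  # greedy engine: approximate symmetry; max asserted over the body core
  # (eroded mask) because the surface shell carries no metric signal
  expect_lt(mean(resid[tpl$mask$values > 0]) / min(g$spacing), 0.3)
  core <- cpp_gauss_smooth(array(as.numeric(tpl$mask$values), g$shape),
                           rep(1.5, 3)) > 0.999
  expect_lt(max(resid[core]) / min(g$spacing), 0.5)
})

test_that("zero-weight labels are effectively ignored", {
  g <- image_grid(c(24, 24, 24), 0.12)
  m1 <- labelmorph:::ellipsoid_mask(g, c(1, 1.4, 1.4), c(0.5, 0.4, 0.4))
  m2 <- labelmorph:::ellipsoid_mask(g, c(2, 1.4, 1.4), c(0.4, 0.4, 0.4))
  vals <- array(0L, g$shape); vals[m1] <- 1L; vals[m2] <- 2L
  fixed_lab <- label_image(g, vals)
  tr <- translation_transform(c(0.2, 0, 0))
  moving_lab <- warp_image(fixed_lab, invert_affine(tr), g, "nearest")
  p <- deformable_params(levels = 2, iters_per_level = c(25, 15))
  r_w0 <- label_metric_refine(fixed_lab, moving_lab,
                              label_params = label_metric_params(
                                weights = c("2" = 0)), params = p)
  # removing label 2 entirely gives (near) the same field where label 1
  # lives
  fl1 <- label_image(g, array(as.integer(vals == 1L), g$shape))
  ml1 <- warp_image(fl1, invert_affine(tr), g, "nearest")
  r_only1 <- label_metric_refine(fl1, ml1, params = p)
  sel <- as.vector(m1)
  d <- matrix(r_w0$forward$vectors - r_only1$forward$vectors,
              prod(g$shape), 3)[sel, ]
  expect_lt(mean(sqrt(rowSums(d^2))) / min(g$spacing), 0.1)
})
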