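# Stage-1 linear alignment: centroid tables, model fits, intensity affine.

test_that("label_centroids matches a brute-force averaging oracle", {
  g <- image_grid(c(16, 16, 16), c(0.5, 0.4, 0.6), origin = c(1, 2, 3))
  set.seed(10)
  vals <- array(0L, g$shape)
  vals[3:5, 3:5, 3:5] <- 1L
  vals[sample(prod(g$shape), 60)] <- 2L
  vals[10:12, 2:4, 8] <- 3L
  lab <- label_image(g, vals)
  tab <- label_centroids(lab)
  pts <- labelmorph:::grid_points(g)
  for (l in label_set(lab)) {
    oracle <- colMeans(pts[as.vector(lab$values == l), , drop = FALSE])
    got <- unlist(tab[tab$label == l, c("c1", "c2", "c3")])
    expect_lt(max(abs(got - oracle)), 1e-9)
  }
  # single centered cube: symmetric centroid
  v2 <- array(0L, c(11, 11, 11))
  v2[5:7, 5:7, 5:7] <- 1L
  g2 <- image_grid(c(11, 11, 11))
  t2 <- label_centroids(label_image(g2, v2))
  expect_equal(unlist(t2[1, c("c1", "c2", "c3")]), c(c1 = 5, c2 = 5,
                                                     c3 = 5))
  expect_error(label_centroids(label_image(g2, array(0L, c(11, 11, 11)))),
               "no nonzero")
})

test_that("centroid fits recover constructed transforms exactly", {
  set.seed(42)
  F <- matrix(runif(15, 0, 10), 5, 3)
  tabF <- centroid_table_from_points(F)

  # translation
  t <- c(1.5, -2, 0.25)
  tabT <- centroid_table_from_points(sweep(F, 2, t, "+"))
  ft <- fit_linear_from_centroids(tabF, tabT, "translation")
  expect_lt(max(abs(apply_transform(ft$transform, F) -
                      sweep(F, 2, t, "+"))), 1e-12)
  expect_lt(ft$rms_residual, 1e-12)

  # rigid: 30 degrees about z around an arbitrary center
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- c(5, 5, 5)
  tabR <- centroid_table_from_points(t(R %*% (t(F) - ctr) + ctr))
  fr <- fit_linear_from_centroids(tabF, tabR, "rigid")
  expect_lt(max(abs(fr$transform$matrix - R)), 1e-8)
  expect_lt(fr$rms_residual, 1e-8)

  # similarity adds one scale
  s <- 1.4
  tabS <- centroid_table_from_points(t(s * R %*% (t(F) - ctr) + ctr))
  fs <- fit_linear_from_centroids(tabF, tabS, "similarity")
  expect_lt(max(abs(fs$transform$matrix - s * R)), 1e-8)

  # affine from 6 affinely independent centroids
  A <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
  F6 <- matrix(runif(18, 0, 10), 6, 3)
  M6 <- t(A %*% t(F6)) + matrix(c(1, 2, 3), 6, 3, byrow = TRUE)
  fa <- fit_linear_from_centroids(centroid_table_from_points(F6),
                                  centroid_table_from_points(M6), "affine")
  expect_lt(max(abs(apply_transform(fa$transform, F6) - M6)), 1e-8)
  expect_false(fa$fallback)
})

test_that("degenerate geometry falls back to a well-posed model, flagged", {
  Fc <- cbind(1:4, 2 * (1:4), 3 * (1:4)) * 1.0   # collinear
  tab <- centroid_table_from_points(Fc)
  tabM <- centroid_table_from_points(sweep(Fc, 2, c(1, 1, 1), "+"))
  fd <- fit_linear_from_centroids(tab, tabM, "affine")
  expect_true(fd$fallback)
  expect_identical(fd$model, "translation")
  # the fallback still matches the data (pure translation)
  expect_lt(fd$rms_residual, 1e-12)

  # 1-2 shared labels: translation only
  f1 <- centroid_table_from_points(matrix(c(1, 2, 3), 1, 3))
  m1 <- centroid_table_from_points(matrix(c(2, 2, 4), 1, 3))
  ff <- fit_linear_from_centroids(f1, m1, "affine")
  expect_identical(ff$model, "translation")
  expect_equal(ff$transform$translation, c(1, 0, 1))
})

test_that("centroid fit is invariant to row order and weight rescaling", {
  set.seed(5)
  F <- matrix(runif(18, 0, 8), 6, 3)
  A <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  M <- t(A %*% t(F)) + 0.3
  w <- runif(6, 0.5, 2)
  tf <- centroid_table_from_points(F, weight = w)
  tm <- centroid_table_from_points(M, weight = 1)
  fit1 <- fit_linear_from_centroids(tf, tm, "affine")

  perm <- sample(6)
  tf2 <- tf[perm, ]; tf2$label <- tf$label[perm]
  tm2 <- tm[perm, ]; tm2$label <- tm$label[perm]
  fit2 <- fit_linear_from_centroids(tf2, tm2, "affine")
  expect_equal(fit1$transform$matrix, fit2$transform$matrix,
               tolerance = 1e-10)

  tf3 <- tf; tf3$weight <- tf$weight * 17
  fit3 <- fit_linear_from_centroids(tf3, tm, "affine")
  expect_equal(fit1$transform$matrix, fit3$transform$matrix,
               tolerance = 1e-10)
  expect_equal(fit1$rms_residual, fit3$rms_residual, tolerance = 1e-10)
})

test_that("rigid fits never return a reflection", {
  set.seed(9)
  for (rep in 1:5) {
    F <- matrix(runif(12, 0, 5), 4, 3)
    M <- F[, c(2, 1, 3)] + matrix(rnorm(12, 0, 0.3), 4, 3)  # swap axes
    fr <- fit_linear_from_centroids(centroid_table_from_points(F),
                                    centroid_table_from_points(M),
                                    "rigid")
    expect_gt(det(fr$transform$matrix), 0)
  }
})

test_that("residuals are ordered affine <= similarity <= rigid", {
  set.seed(11)
  F <- matrix(runif(24, 0, 10), 8, 3)
  M <- t((diag(3) + matrix(rnorm(9, 0, 0.2), 3, 3)) %*% t(F)) +
    matrix(rnorm(24, 0, 0.4), 8, 3)
  tf <- centroid_table_from_points(F)
  tm <- centroid_table_from_points(M)
  r_r <- fit_linear_from_centroids(tf, tm, "rigid")$rms_residual
  r_s <- fit_linear_from_centroids(tf, tm, "similarity")$rms_residual
  r_a <- fit_linear_from_centroids(tf, tm, "affine")$rms_residual
  expect_lte(r_a, r_s + 1e-12)
  expect_lte(r_s, r_r + 1e-12)
})

test_that("intensity linear registration recovers known translations", {
  tpl <- small_phantom()
  g <- tpl$intensity$grid
  # fixed == moving: identity within 0.05 voxel
  f0 <- intensity_linear_register(tpl$intensity, tpl$intensity,
                                  mask = tpl$mask, model = "translation")
  expect_lt(max(abs(f0$transform$translation)) / min(g$spacing), 0.05)

  # known 3.4-voxel translation recovered within 0.5 voxel
  t_true <- c(3.4, 0, -2) * g$spacing
  clean <- labelmorph:::clean_template_intensity(tpl)
  mv <- warp_image(clean, invert_affine(translation_transform(t_true)),
                   g, "linear")
  ft <- intensity_linear_register(tpl$intensity, mv, mask = tpl$mask,
                                  model = "translation")
  expect_lt(max(abs(ft$transform$translation - t_true)) / min(g$spacing),
            0.5)

  # heavy corruption outside the (moving-space) body barely moves the
  # estimate: masked voxels never sample it under a correct alignment
  mv_mask <- warp_image(tpl$mask, invert_affine(translation_transform(
    t_true)), g, "nearest")
  # guard band: keep a ~3-voxel margin clean so interpolation at the body
  # surface never touches corrupted voxels
  dil <- cpp_gauss_smooth(array(as.numeric(mv_mask$values), g$shape),
                          rep(1.5, 3))
  corrupted <- mv$values
  outside <- dil < 1e-4
  set.seed(1)
  corrupted[outside] <- rnorm(sum(outside), 200, 150)
  fc <- intensity_linear_register(tpl$intensity,
                                  scalar_image(g, corrupted),
                                  mask = tpl$mask, model = "translation")
  expect_lt(max(abs(fc$transform$translation -
                      ft$transform$translation)) / min(g$spacing), 0.1)

  expect_error(intensity_linear_register(
    tpl$intensity, mv,
    mask = label_image(g, array(0L, g$shape))), "empty mask")
})
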