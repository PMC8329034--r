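test_that("a coplanar skeleton lofts to an exactly planar patch", {
  p <- plate_preset("A")
  p$h[] <- 0
  grid <- build_feature_points(p, plane_surface(300), heights = "parametric")
  patch <- loft_undersurface(build_skeleton(grid))
  q <- expand.grid(u = seq(0, 1, length.out = 21), v = seq(0, 1, length.out = 9))
  pts <- patch_eval(patch, q$u, q$v)
  expect_lt(max(abs(pts[, 1])), 1e-9)
})

test_that("the patch interpolates every skeleton sample point", {
  d <- mean_design()
  grid <- d$grid
  patch <- d$patch
  worst <- 0
  for (i in 1:11) {
    got <- patch_eval(patch, rep(patch$u[i], 9), patch$v)
    worst <- max(worst, max(abs(got - matrix(grid$points[i, , ], ncol = 3))))
  }
  expect_lt(worst, 1e-6)
})

test_that("a cylinder-sampled skeleton reproduces the cylinder radius between stations", {
  # synthetic cylinder surface via a zero-bump straight femur
  p <- mean_femur_parameters()
  p["H_t1"] <- 0
  p["A_fs"] <- 180
  surf <- generate_bone_surface(p, resolution = 12)
  sem <- semantic_parameters(l1 = 229, l2 = 39, w = rep(16, 9), h = rep(0, 9))
  grid <- build_feature_points(sem, surf, heights = "measured")
  # uniform station widths: resample every profile at the same 16 mm arc
  grid$stations$width[] <- 16
  for (i in 1:11) {
    s <- grid$s_off + grid$stations$z[i]
    grid$points[i, , ] <- femplate:::surface_point(surf, rep(s, 9),
                                                   seq(-8, 8, length.out = 9))
  }
  patch <- loft_undersurface(build_skeleton(grid))
  set.seed(2)
  probe <- patch_eval(patch, runif(60, 0.05, 0.95), runif(60, 0.05, 0.95))
  rad <- sqrt(probe[, 1]^2 + probe[, 2]^2) # cylinder axis is the z axis
  expect_equal(rad, rep(p[["D_fs"]] / 2, 60), tolerance = 1e-3 / 13)
})

test_that("fit deviation of the generating skeleton points is essentially zero", {
  d <- mean_design()
  pts <- do.call(rbind, lapply(1:11, function(i) matrix(d$grid$points[i, , ], ncol = 3)))
  fit <- fit_deviation(d$patch, pts)
  expect_lt(attr(fit, "max"), 1e-6)
})

test_that("a rigidly offset plane of points reads back as exactly that offset", {
  p <- plate_preset("A")
  p$h[] <- 0
  grid <- build_feature_points(p, plane_surface(300), heights = "parametric")
  patch <- loft_undersurface(build_skeleton(grid))
  q <- expand.grid(u = seq(0.1, 0.9, length.out = 10), v = seq(0.2, 0.8, length.out = 5))
  pts <- patch_eval(patch, q$u, q$v)
  pts[, 1] <- pts[, 1] + 1.0 # 1 mm along the plane normal
  fit <- fit_deviation(patch, pts)
  expect_equal(attr(fit, "max"), 1.0, tolerance = 1e-6)
  expect_equal(attr(fit, "mean"), 1.0, tolerance = 1e-6)
})

test_that("fit reports are invariant under rigid motion of the whole scene", {
  d <- mean_design()
  contact <- sample_contact_points(d$grid, n_axial = 10, n_transverse = 8)
  fit1 <- fit_deviation(d$patch, contact)
  rot <- rotation_matrix(c(1, 0.3, -0.5), 1.1)
  shift <- c(-7, 4, 12)
  g2 <- transform_grid(d$grid, rot, shift)
  patch2 <- loft_undersurface(build_skeleton(g2))
  fit2 <- fit_deviation(patch2, transform_points(contact, rot, shift))
  expect_lt(max(abs(fit1$distance - fit2$distance)), 1e-9)
  expect_lt(abs(attr(fit1, "max") - attr(fit2, "max")), 1e-9)
})

test_that("halving the transverse resolution degrades the fit monotonically and boundedly", {
  d <- mean_design()
  full <- attr(d$fit, "max")
  g5 <- build_feature_points(d$semantic, d$surface, n_profile = 5)
  p5 <- loft_undersurface(build_skeleton(g5))
  f5 <- fit_deviation(p5, sample_contact_points(d$grid))
  expect_gte(attr(f5, "max"), full - 1e-6)
  expect_lte(attr(f5, "max"), 2 * full)
})

test_that("fit report summaries satisfy max >= mean >= 0 and glance matches", {
  d <- mean_design()
  fit <- d$fit
  expect_gte(attr(fit, "max"), attr(fit, "mean"))
  expect_gte(attr(fit, "mean"), 0)
  g <- glance(fit)
  expect_equal(g$max, attr(fit, "max"))
  expect_equal(g$n, nrow(fit))
  expect_s3_class(autoplot(fit), "ggplot")
})
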