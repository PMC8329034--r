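test_that("a flat plane with zero heights gives a coplanar grid", {
  p <- plate_preset("A")
  p$h[] <- 0
  grid <- build_feature_points(p, plane_surface(300), heights = "parametric")
  xs <- grid$points[, , 1]
  expect_lt(max(abs(xs)), 1e-12)
  expect_equal(grid$stations$height_attained, rep(0, 11), tolerance = 1e-12)
})

test_that("doubling a station width doubles that station's profile chord on a plane", {
  p1 <- plate_preset("A")
  g1 <- build_feature_points(p1, plane_surface(300))
  p2 <- plate_preset("A")
  p2$w[["w5"]] <- 2 * p2$w[["w5"]]
  p2$W <- max(p2$w)
  g2 <- build_feature_points(p2, plane_surface(300))
  chord <- function(g, i) sqrt(sum((g$points[i, 9, ] - g$points[i, 1, ])^2))
  # w5 drives station 7 (tail tip, w0, w1, w2, w3, w4, w5, ...)
  expect_equal(chord(g2, 7), 2 * chord(g1, 7), tolerance = 1e-6)
  expect_equal(chord(g2, 3), chord(g1, 3), tolerance = 1e-9)
})

test_that("the mean-femur grid has 11 stations, the exact axial extent, and lies on the bone", {
  d <- mean_design()
  grid <- d$grid
  expect_equal(nrow(grid$stations), 11L)
  expect_equal(grid_extent(grid), d$semantic$l1 + d$semantic$l2, tolerance = 1e-6)
  # every grid point is an exact surface sample
  for (i in c(1, 4, 7, 11)) {
    s <- grid$s_off + grid$stations$z[i]
    w <- grid$stations$width[i]
    ref <- femplate:::surface_point(d$surface, rep(s, 9),
                                    seq(-1, 1, length.out = 9) * w / 2)
    expect_lt(max(abs(matrix(grid$points[i, , ], ncol = 3) - ref)), 1e-3)
  }
})

test_that("footprints larger than the contact region are refused with the overhang", {
  long <- plate_preset("A")
  surf <- generate_bone_surface(mean_femur_parameters(), resolution = 12)
  long$l1 <- 400
  long$L <- long$l1 + long$l2
  expect_error(build_feature_points(long, surf), "exceeds contact region")
})

test_that("skeleton construction needs all 11 stations", {
  g <- build_feature_points(plate_preset("A"), plane_surface(300))
  g$stations <- g$stations[1:9, ]
  expect_error(build_skeleton(g), "11 stations")
})

test_that("the skeleton is rigidly equivariant and the ridges share one junction point", {
  g <- build_feature_points(plate_preset("A"), plane_surface(300))
  skel <- build_skeleton(g)
  rot <- rotation_matrix(c(0, 1, 2), 0.4)
  shift <- c(3, -2, 10)
  g2 <- transform_grid(g, rot, shift)
  skel2 <- build_skeleton(g2)
  for (id in names(skel)) {
    expect_equal(skel2[[id]]$points,
                 transform_points(skel[[id]]$points, rot, shift),
                 tolerance = 1e-9)
  }
  # tail and head ridges meet end-to-end exactly once
  expect_equal(skel$C1$points[4, ], skel$C2$points[1, ])
  d_other <- min(sqrt(rowSums(sweep(skel$C2$points[-1, ], 2,
                                    skel$C1$points[4, ])^2)))
  expect_gt(d_other, 1)
})

test_that("tail costals attach to the tail ridge and head costals to the head ridge", {
  skel <- eagle_template_cached()
  expect_equal(classify_relation(skel$C1, skel$C10), "II_13")
  expect_equal(classify_relation(skel$C2, skel$C3), "II_13")
  expect_equal(classify_relation(skel$C1, skel$C3), "II_0")
  expect_equal(classify_relation(skel$C1, skel$C9), "II_12")
})
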