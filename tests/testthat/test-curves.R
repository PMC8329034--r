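test_that("feature curves validate their invariants", {
  pts <- cbind(0:4, 0, 0)
  cv <- feature_curve(pts, id = "X")
  expect_equal(cv$kind, "internal")
  expect_false(cv$closed)
  expect_error(feature_curve(pts[1:3, ]), "at least 4")
  expect_error(feature_curve(pts[c(1, 2, 2, 3), ]), "duplicate")
  b <- rect_boundary()
  expect_true(b$closed)
})

test_that("disjoint parallel segments do not intersect", {
  c1 <- segment_curve(c(0, 0, 0), c(10, 0, 0))
  c2 <- segment_curve(c(0, 2, 0), c(10, 2, 0))
  expect_equal(nrow(intersection_profile(c1, c2)), 0L)
  expect_equal(classify_relation(c1, c2), "II_0")
})

test_that("segments sharing a terminus give one endpoint-endpoint hit", {
  c1 <- segment_curve(c(0, 0, 0), c(5, 0, 0))
  c2 <- segment_curve(c(5, 0, 0), c(8, 4, 0))
  h <- intersection_profile(c1, c2)
  expect_equal(nrow(h), 1L)
  expect_equal(h$class, "endpoint-endpoint")
  expect_equal(c(h$x, h$y, h$z), c(5, 0, 0), tolerance = 1e-9)
  expect_equal(classify_relation(c1, c2), "II_11")
})

test_that("an X crossing is found at the analytic intersection point", {
  c1 <- segment_curve(c(-5, -5, 0), c(5, 5, 0))
  c2 <- segment_curve(c(-5, 5, 0), c(5, -5, 0))
  h <- intersection_profile(c1, c2)
  expect_equal(nrow(h), 1L)
  expect_equal(h$class, "interior-interior")
  expect_equal(c(h$x, h$y, h$z), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(classify_relation(c1, c2), "II_13")
})

test_that("an endpoint landing mid-curve classifies as endpoint-interior", {
  c1 <- segment_curve(c(-5, 0, 0), c(5, 0, 0))
  c2 <- segment_curve(c(1, 0, 0), c(4, 6, 0))
  h <- intersection_profile(c1, c2)
  expect_equal(nrow(h), 1L)
  expect_equal(h$class, "endpoint-interior")
  expect_equal(classify_relation(c1, c2), "II_12")
})

test_that("colinear overlap of positive length is a degenerate error", {
  c1 <- segment_curve(c(0, 0, 0), c(10, 0, 0), n = 9)
  c2 <- segment_curve(c(3, 0, 0), c(12, 0, 0), n = 9)
  expect_error(intersection_profile(c1, c2), "degenerate overlap")
})

test_that("boundary-internal relations count intersections; two boundaries are refused", {
  b <- rect_boundary()
  inside <- segment_curve(c(-3, -2, 0), c(3, 2, 0))
  expect_equal(classify_relation(b, inside), "BI_0")
  one_end <- segment_curve(c(-10, 0, 0), c(0, 3, 0)) # starts on the boundary
  expect_equal(classify_relation(b, one_end), "BI_11")
  chord <- segment_curve(c(-10, 0, 0), c(10, 0, 0)) # both ends on the boundary
  expect_equal(classify_relation(b, chord), "BI_21")
  expect_error(classify_relation(b, rect_boundary(5, 3, id = "B1")), "single boundary")
})

test_that("relation classification is symmetric", {
  b <- rect_boundary()
  chord <- segment_curve(c(-10, 0, 0), c(10, 0, 0))
  cross1 <- segment_curve(c(-5, -5, 0), c(5, 5, 0))
  cross2 <- segment_curve(c(-5, 5, 0), c(5, -5, 0))
  pairs <- list(list(b, chord), list(cross1, cross2), list(b, cross1))
  for (pr in pairs) {
    expect_identical(classify_relation(pr[[1]], pr[[2]]),
                     classify_relation(pr[[2]], pr[[1]]))
  }
})

test_that("topology matrix of a trivial arrangement and its permutation equivariance", {
  b <- rect_boundary(12, 8)
  i1 <- segment_curve(c(-4, -3, 0), c(-1, -3, 0), id = "I1")
  i2 <- segment_curve(c(1, 3, 0), c(4, 3, 0), id = "I2")
  m <- topology_matrix(list(b, i1, i2))
  expect_equal(unname(diag(m)), c("B", "I", "I"))
  expect_equal(unname(m[1, 2]), "BI_0")
  expect_equal(unname(m[2, 3]), "II_0")
  m_perm <- topology_matrix(list(i2, b, i1))
  expect_equal(unname(unclass(m_perm)[c(2, 3, 1), c(2, 3, 1)]), unname(unclass(m)))
  expect_error(topology_matrix(list(i1, i2)), "exactly one boundary")
})

test_that("topology diffs are empty on identity and pinpoint a single flipped cell", {
  ref <- eagle_topology_reference()
  expect_equal(nrow(validate_topology(ref, ref)), 0L)
  mod <- ref
  mod["C3", "C4"] <- mod["C4", "C3"] <- "II_13"
  d <- validate_topology(mod, ref)
  expect_equal(nrow(d), 1L)
  expect_equal(d$found, "II_13")
  expect_equal(d$expected, "II_0")
  expect_error(validate_topology(ref, structure(ref[1:4, 1:4], class = class(ref))),
               "dimensions")
})

test_that("the published adjacency matrix has the expected structure", {
  ref <- eagle_topology_reference()
  expect_equal(dim(ref), c(12L, 12L))
  expect_equal(unname(diag(ref)), c("B", rep("I", 11)))
  expect_equal(unname(ref["C0", "C1"]), "BI_11")
  expect_true(all(ref["C0", paste0("C", 3:11)] == "BI_21"))
  expect_equal(unname(ref["C1", "C2"]), "II_11")
  expect_equal(unname(ref["C2", "C9"]), "II_12")
  expect_true(all(ref[upper.tri(ref)] == t(ref)[upper.tri(ref)]))
})
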