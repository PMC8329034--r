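test_that("published plate presets satisfy every hierarchy identity", {
  for (w in c("A", "B", "C")) {
    p <- plate_preset(w)
    v <- check_dimension_constraints(p, stats = NULL)
    expect_equal(nrow(v), 0L)
    expect_equal(p$L, p$l1 + p$l2)
  }
  a <- plate_preset("A")
  expect_equal(a$l1, 229)
  expect_equal(a$l2, 39)
  expect_equal(a$w[["w0"]], 12)
  expect_equal(a$w[["w5"]], 29)
  expect_equal(a$d1, 7)
  expect_equal(a$s1, 6)
  expect_equal(a$t1, 3)
  b <- plate_preset("B")
  expect_equal(c(b$l1, b$l2), c(204, 44))
})

test_that("hierarchy violations are reported as data, one per broken rule", {
  p <- plate_preset("A")
  p$L <- p$L + 1 # break L = l1 + l2
  v <- check_dimension_constraints(p, stats = NULL)
  expect_equal(v$parameter, "L")
  p2 <- plate_preset("A")
  p2$w[["w5"]] <- p2$W + 5
  v2 <- check_dimension_constraints(p2, stats = NULL)
  expect_equal(v2$parameter, "w5")
  expect_match(v2$rule, "total width")
  p3 <- plate_preset("A")
  p3$h[["h3"]] <- -1
  expect_equal(check_dimension_constraints(p3, stats = NULL)$parameter, "h3")
})

test_that("the reference mean femur derives the published Plate A dimensions", {
  sem <- derive_semantic_parameters(mean_femur_parameters())
  expect_equal(sem$L, 268, tolerance = 1e-9)
  expect_equal(sem$l1, 229, tolerance = 1e-9)
  expect_equal(sem$l2, 39, tolerance = 1e-9)
  expect_equal(unname(sem$w), unname(plate_preset("A")$w), tolerance = 1e-9)
  expect_equal(unname(sem$h), unname(plate_preset("A")$h), tolerance = 1e-9)
})

test_that("plate length is linear in femur length and zero lengths are refused", {
  base <- derive_semantic_parameters(mean_femur_parameters(), stats = NULL)
  doubled <- mean_femur_parameters()
  doubled["H_f"] <- doubled["H_f"] * 2
  sem2 <- derive_semantic_parameters(doubled, stats = NULL)
  expect_equal(sem2$L, 2 * base$L)
  bad <- mean_femur_parameters()
  bad["H_f"] <- 0
  expect_error(derive_semantic_parameters(bad), "positive")
})

test_that("out-of-range derived parameters raise an error naming the violations", {
  big <- mean_femur_parameters()
  big["H_f"] <- big["H_f"] * 1.5 # ~9 SD: outside the +/-3 SD admissible band
  expect_error(derive_semantic_parameters(big), "constraint.*L|L.*constraint")
})

test_that("zero component scores reproduce the base mean-shape plate bit-for-bit", {
  mapping <- component_mapping()
  sem <- apply_component_mapping(rep(0, 11), mapping)
  expect_identical(sem, mapping$base)
})

test_that("a positive score on the proximal size component widens every station", {
  mapping <- component_mapping()
  base <- mapping$base
  sem <- apply_component_mapping(c(2, rep(0, 10)), mapping)
  expect_true(all(sem$w > base$w))
  expect_equal(order(sem$w), order(base$w)) # ordering preserved
})

test_that("distal scores also move the derived plate (all of P4 is active)", {
  mapping <- component_mapping()
  sem <- apply_component_mapping(c(rep(0, 4), 1.5, rep(0, 6)), mapping)
  expect_false(isTRUE(all.equal(unname(sem$w), unname(mapping$base$w))))
})

test_that("the component mapping is continuous in every score", {
  mapping <- component_mapping()
  eps <- 1e-6
  base <- apply_component_mapping(rep(0, 11), mapping)
  for (i in c(1, 4, 5, 11)) {
    s <- rep(0, 11)
    s[i] <- eps
    sem <- apply_component_mapping(s, mapping)
    delta <- max(abs(c(sem$L - base$L, sem$w - base$w, sem$h - base$h)))
    expect_lt(delta, 1e-3) # O(eps) with bounded sensitivity
  }
})

test_that("rotated loadings are refused by the mapping", {
  expect_error(component_mapping(proximal = rotate_loadings(proximal_loadings())),
               "raw")
})

test_that("distinct score sets give distinct parameter sets with unchanged topology", {
  mapping <- component_mapping()
  set.seed(13)
  sems <- lapply(1:5, function(i) {
    apply_component_mapping(rnorm(11, sd = 0.6), mapping)
  })
  keys <- vapply(sems, function(s) paste(signif(unlist(s[c("L", "w", "h")]), 10),
                                         collapse = ","), "")
  expect_equal(length(unique(keys)), 5L)
  ref <- eagle_topology_reference()
  for (i in c(1, 4)) { # topology check on a subset (it is the slow step)
    skel <- build_skeleton(build_feature_points(sems[[i]], plane_surface(300),
                                                heights = "parametric"))
    m <- topology_matrix(unname(unclass(skel)))
    expect_equal(nrow(validate_topology(m, ref)), 0L)
  }
})

test_that("semantic parameter sets round-trip through JSON", {
  p <- plate_preset("C")
  path <- withr::local_tempfile(fileext = ".json")
  write_semantic_json(p, path)
  back <- read_semantic_json(path)
  expect_equal(back$L, p$L)
  expect_equal(back$w, p$w)
  expect_equal(back$h, p$h)
  expect_equal(back$s1, p$s1)
})
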