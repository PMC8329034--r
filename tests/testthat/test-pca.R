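test_that("eigendecomposition: identity and rank-one cases, sign convention, rate sums", {
  e <- pca_eigen(diag(5))
  expect_equal(e$values, rep(1, 5))
  expect_equal(sum(e$rates), 1)
  v <- c(3, -1, 2, 0.5)
  v <- v / sqrt(sum(v^2))
  e2 <- pca_eigen(2.5 * tcrossprod(v))
  expect_equal(e2$values[1], 2.5)
  expect_equal(e2$values[-1], rep(0, 3), tolerance = 1e-12)
  # sign convention: largest-magnitude entry positive
  expect_gt(e2$vectors[which.max(abs(e2$vectors[, 1])), 1], 0)
  expect_equal(abs(e2$vectors[, 1]), abs(v))
})

test_that("eigenvalues of a correlation matrix sum to p and vectors are orthonormal", {
  set.seed(5)
  r <- random_correlation(7)
  e <- pca_eigen(r)
  expect_equal(sum(e$values), 7, tolerance = 1e-6)
  expect_equal(crossprod(e$vectors), diag(7), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(e$cumulative[7], 1, tolerance = 1e-10)
})

test_that("rank-4 reconstruction from published proximal loadings has the published spectrum", {
  a <- unclass(proximal_loadings())
  a <- a / sqrt(rowSums(a^2))
  lam <- proximal_rates() * 9
  r0 <- crossprod(a * sqrt(lam)) # construction oracle: spectrum is lam by design
  e <- pca_eigen(r0)
  expect_equal(e$values[1:4], c(3.875, 2.290, 1.276, 0.702), tolerance = 0.05 / 0.7)
  # full repaired reconstruction stays close to the published spectrum
  rr <- reconstruct_correlation(proximal_loadings(), proximal_rates())
  er <- pca_eigen(rr)
  expect_equal(er$values[1:4], lam, tolerance = 0.1)
})

test_that("retention rule reproduces the published component counts", {
  prox <- eigen_system(proximal_rates() * 9, p = 9)
  expect_equal(as.integer(retain_components(prox)), 4L)
  dist <- eigen_system(distal_rates() * 16, p = 16)
  expect_equal(as.integer(retain_components(dist)), 7L)
  expect_gt((distal_rates() * 16)[7], 0.5) # lambda7 = 0.695 clears the floor
})

test_that("retention boundary is inclusive and the eigenvalue floor wins conflicts", {
  eq <- eigen_system(rep(1, 10), p = 10)
  expect_equal(as.integer(retain_components(eq)), 9L) # 9/10 = 0.90 meets >=
  conflicted <- eigen_system(c(2, 0.45, 0.45, 0.45), p = 4)
  expect_warning(k <- retain_components(conflicted), "floor wins")
  expect_equal(as.integer(k), 1L)
  expect_true(attr(k, "floor_limited"))
  expect_error(retain_components(eigen_system(c(0.1, 0.1), p = 2)), "floor")
})

test_that("retention is monotone in the variance threshold", {
  set.seed(21)
  for (rep in 1:10) {
    e <- pca_eigen(random_correlation(8))
    ks <- vapply(seq(0.5, 0.999, length.out = 12), function(th) {
      as.integer(suppressWarnings(retain_components(e, var_threshold = th)))
    }, 0L)
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("component scores are the plain loading-vector product", {
  a <- proximal_loadings()
  e1 <- c(1, rep(0, 8))
  expect_equal(unname(component_scores(e1, a)), c(0.348, 0.291, 0.384, 0.289))
  expect_equal(unname(component_scores(rep(0, 9), a)), rep(0, 4))
  # first published eigenvector scores ~ (1, 0, 0, 0) by row orthonormality
  v1 <- unclass(a)[1, ]
  s <- component_scores(v1, a)
  expect_equal(unname(s[1]), 1.001, tolerance = 0.05)
  expect_lt(max(abs(s[2:4])), 0.05)
  expect_error(component_scores(rep(0, 5), a), "length")
})

test_that("varimax rotation preserves communalities and Frobenius norm", {
  set.seed(31)
  for (rep in 1:5) {
    a <- loading_matrix(matrix(rnorm(3 * 8), 3, 8))
    rot <- rotate_loadings(a)
    expect_true(is_rotated(rot))
    expect_equal(communalities(rot), communalities(a), tolerance = 1e-8)
    expect_equal(sum(unclass(rot)^2), sum(unclass(a)^2), tolerance = 1e-8)
  }
})

test_that("varimax beats 1000 random orthogonal rotations on the criterion", {
  set.seed(8)
  a <- matrix(rnorm(3 * 6), 3, 6)
  an <- sweep(a, 2, sqrt(colSums(a^2)), "/") # Kaiser normalization commutes
  rot <- rotate_loadings(loading_matrix(a))
  rn <- sweep(unclass(rot), 2, sqrt(colSums(unclass(rot)^2)), "/")
  crit <- varimax_criterion(rn)
  worst <- 0
  for (i in 1:1000) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    worst <- max(worst, varimax_criterion(t(q) %*% an))
  }
  expect_gte(crit + 1e-8, worst)
})

test_that("a perfect simple structure is a varimax fixed point up to sign/order", {
  a <- loading_matrix(rbind(c(1, 1, 0, 0) / sqrt(2), c(0, 0, 1, 1) / sqrt(2)))
  rot <- rotate_loadings(a)
  m <- abs(unclass(rot))
  expect_equal(sort(round(as.vector(m), 6)), sort(round(abs(as.vector(unclass(a))), 6)),
               tolerance = 1e-6)
})

test_that("single-component rotation is the identity with a note", {
  a <- loading_matrix(matrix(rnorm(6), 1, 6))
  rot <- rotate_loadings(a)
  expect_equal(unclass(rot), unclass(a), ignore_attr = TRUE)
  expect_match(attr(rot, "note"), "single component")
})

test_that("dominant-parameter assignment matches a brute-force argmax and flags ties", {
  ident <- loading_matrix(diag(4), variables = letters[1:4], rotated = TRUE)
  d <- dominant_parameters(ident)
  expect_equal(d$component, 1:4)
  set.seed(17)
  m <- loading_matrix(matrix(rnorm(3 * 7), 3, 7), rotated = TRUE)
  d2 <- dominant_parameters(m)
  expect_equal(d2$component, unname(apply(abs(unclass(m)), 2, which.max)))
  tied <- loading_matrix(rbind(c(0.5, 0.9), c(0.5, 0.1)), rotated = TRUE)
  d3 <- dominant_parameters(tied)
  expect_equal(d3$component[1], 1L)
  expect_true(d3$tied[1])
})

test_that("a planted simple structure is recovered after rotation", {
  # four parameters loading 0.9 on component 1, the rest elsewhere
  set.seed(4)
  targets <- c("D_fh", "D_fn", "L_t", "H_t1")
  params <- region_parameters("proximal")
  a <- matrix(rnorm(2 * 9, sd = 0.05), 2, 9)
  a[1, match(targets, params)] <- 0.9
  a[2, setdiff(seq_len(9), match(targets, params))] <- 0.8
  rot <- rotate_loadings(loading_matrix(a, variables = params))
  d <- dominant_parameters(rot)
  comp1 <- d$parameter[d$component == d$component[d$parameter == "D_fh"]]
  expect_setequal(intersect(comp1, targets), targets)
})

test_that("reconstruction is the orthogonal projection onto retained components", {
  a <- proximal_loadings()
  expect_equal(unname(reconstruct_parameters(rep(0, 4), a)), rep(0, 9))
  set.seed(12)
  x <- rnorm(9)
  xh <- reconstruct_parameters(component_scores(x, a), a)
  expect_lte(sqrt(sum(xh^2)), sqrt(sum(x^2)) * (1 + 1e-3))
  rot <- rotate_loadings(a)
  expect_error(reconstruct_parameters(rep(0, 4), rot), "raw")
})

test_that("exact orthonormal loadings give an exact projection identity", {
  set.seed(3)
  q <- qr.Q(qr(matrix(rnorm(81), 9, 9)))[, 1:4]
  a <- loading_matrix(t(q))
  x <- drop(q %*% rnorm(4)) # in the span
  expect_equal(reconstruct_parameters(component_scores(x, a), a), x,
               tolerance = 1e-8, ignore_attr = TRUE)
  y <- rnorm(9)
  resid <- y - reconstruct_parameters(component_scores(y, a), a)
  expect_lt(max(abs(drop(t(q) %*% resid))), 1e-8)
})
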