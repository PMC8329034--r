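# Shared fixtures. Expensive objects are built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

mean_design <- function() {
  cached("mean_design", function() design_plate(mean_femur_parameters()))
}

eagle_template_cached <- function() {
  cached("eagle_template", eagle_template)
}

# rotation by angle around a (unit) axis, Rodrigues form
rotation_matrix <- function(axis = c(1, 1, 1), angle = 0.7) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * kx + (1 - cos(angle)) * kx %*% kx
}

transform_points <- function(p, rot, shift = c(0, 0, 0)) {
  sweep(p %*% t(rot), 2L, -shift)
}

# rigidly move every point of a feature grid (points only; the surface
# reference is dropped, which downstream loft/fit code never touches)
transform_grid <- function(grid, rot, shift = c(0, 0, 0)) {
  for (i in seq_len(dim(grid$points)[1L])) {
    grid$points[i, , ] <- transform_points(matrix(grid$points[i, , ], ncol = 3L),
                                           rot, shift)
  }
  grid
}

# straight line segment as a feature curve (n points)
segment_curve <- function(from, to, n = 5L, id = NULL, kind = "internal") {
  t <- seq(0, 1, length.out = n)
  feature_curve(outer(1 - t, from) + outer(t, to), kind = kind, id = id)
}

# axis-aligned rectangle boundary curve in the z = 0 plane
rect_boundary <- function(half_w = 10, half_h = 6, id = "B0") {
  corners <- rbind(
    c(-half_w, -half_h, 0), c(0, -half_h, 0), c(half_w, -half_h, 0),
    c(half_w, 0, 0), c(half_w, half_h, 0), c(0, half_h, 0),
    c(-half_w, half_h, 0), c(-half_w, 0, 0)
  )
  feature_curve(corners, kind = "boundary", id = id)
}

# random PSD correlation matrix of dimension p
random_correlation <- function(p, df = p + 3) {
  x <- matrix(stats::rnorm(df * p), df, p)
  stats::cov2cor(crossprod(x) / df + diag(0.2, p))
}
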