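#' Loft the plate undersurface through the skeleton
#'
#' Tensor-product cubic interpolation through the costal-curve sample
#' points (the full station x profile grid), chord-length parameterized in
#' both directions. Internally the patch is stored in cardinal-basis form:
#' cubic interpolation with fixed knots is linear in the data, so
#' \eqn{S(u,v) = \sum_{ij} N_i(u) M_j(v) P_{ij}} with one precomputed
#' cardinal spline per knot, which makes evaluation fully vectorized. The
#' patch passes through every skeleton sample point exactly (to numerical
#' precision) and is C1 across the interior.
#'
#' @param skel A `skeleton_curves` object from [build_skeleton()] (the
#'   generating grid travels with it).
#' @return An `undersurface_patch`.
#' @export
loft_undersurface <- function(skel) {
  grid <- attr(skel, "grid")
  if (is.null(grid)) stop("skeleton carries no generating grid", call. = FALSE)
  pts <- grid$points
  ns <- dim(pts)[1L]
  np <- dim(pts)[2L]
  apex <- (np + 1L) / 2L
  # chord-length knots: along the apex line (u), averaged across profiles (v)
  apexes <- matrix(pts[, apex, ], ncol = 3L)
  du <- sqrt(rowSums((apexes[-1L, , drop = FALSE] - apexes[-ns, , drop = FALSE])^2))
  u <- c(0, cumsum(du)) / sum(du)
  ch <- matrix(0, ns, np - 1L)
  for (i in seq_len(ns)) {
    p <- matrix(pts[i, , ], ncol = 3L)
    ch[i, ] <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-np, , drop = FALSE])^2))
  }
  dv <- colMeans(ch)
  v <- c(0, cumsum(dv)) / sum(dv)
  patch <- structure(
    list(points = pts, u = u, v = v, grid = grid),
    class = "undersurface_patch"
  )
  check_loft_regularity(patch)
  patch
}

# Local cubic Hermite interpolation on a nonuniform knot vector. Every
# knot tangent is the derivative of a quadratic Lagrange polynomial; the
# stencil is the two neighbours (classic three-point slope) except at
# strongly nonuniform knots -- the plate's tail/head junction, where a
# 76 mm tail span meets 5.6 mm head spans -- where it is taken one-sided
# from the longer-span side. A centered slope there is dominated by the
# short-span side and makes the long Hermite segment sag by hundreds of
# microns; the one-sided slope reproduces the smooth long-side geometry
# exactly to second order. Linear in the data (so cardinal-basis
# evaluation is exact), C1, and strictly local.
tangent_weights <- function(knots) {
  n <- length(knots)
  w <- matrix(0, n, n)
  lagr_deriv_w <- function(xs, x0) {
    vapply(seq_along(xs), function(j) {
      others <- xs[-j]
      s <- sum(vapply(seq_along(others), function(m) {
        prod(x0 - others[-m])
      }, 0))
      s / prod(xs[j] - others)
    }, 0)
  }
  if (n == 2L) {
    d <- knots[2L] - knots[1L]
    return(matrix(c(-1, -1, 1, 1) / d, 2L, 2L))
  }
  for (i in seq_len(n)) {
    idx <- if (i == 1L) {
      1:3
    } else if (i == n) {
      (n - 2L):n
    } else {
      hl <- knots[i] - knots[i - 1L]
      hr <- knots[i + 1L] - knots[i]
      if (hl > 2 * hr && i > 2L) {
        (i - 2L):i
      } else if (hr > 2 * hl && i < n - 1L) {
        i:(i + 2L)
      } else {
        (i - 1L):(i + 1L)
      }
    }
    w[i, idx] <- lagr_deriv_w(knots[idx], knots[i])
  }
  w
}

cr_eval <- function(knots, y, x) {
  y <- as.matrix(y)
  m <- tangent_weights(knots) %*% y
  k <- findInterval(x, knots, all.inside = TRUE)
  h <- knots[k + 1L] - knots[k]
  t <- (x - knots[k]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[k, , drop = FALSE] + (h10 * h) * m[k, , drop = FALSE] +
    h01 * y[k + 1L, , drop = FALSE] + (h11 * h) * m[k + 1L, , drop = FALSE]
}

# cardinal basis values at query parameters: n x n_knots matrix
cr_basis <- function(knots, x) {
  cr_eval(knots, diag(length(knots)), x)
}

#' Evaluate an undersurface patch
#'
#' @param patch An `undersurface_patch`.
#' @param u,v Normalized surface parameters in `[0, 1]` (recycled).
#' @return Matrix n x 3 of points (mm).
#' @export
patch_eval <- function(patch, u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n)
  v <- rep_len(v, n)
  nu <- cr_basis(patch$u, u)
  nv <- cr_basis(patch$v, v)
  out <- matrix(0, n, 3L)
  for (k in 1:3) {
    out[, k] <- rowSums((nu %*% patch$points[, , k]) * nv)
  }
  out
}

# Jacobian sign-flip guard on a sample grid: a self-intersecting loft flips
# the orientation of the tangent-plane normal somewhere
check_loft_regularity <- function(patch, nu = 21L, nv = 9L) {
  q <- expand.grid(u = seq(0, 1, length.out = nu),
                   v = seq(0, 1, length.out = nv))
  nr <- patch_raw_normal(patch, q$u, q$v)
  len <- sqrt(rowSums(nr^2))
  if (any(len < 1e-12)) {
    stop("degenerate loft: vanishing tangent plane on the sample grid", call. = FALSE)
  }
  nr <- nr / len
  dim(nr) <- c(nu, nv, 3L)
  dots_u <- rowSums(nr[-1L, , , drop = FALSE] * nr[-nu, , , drop = FALSE], dims = 2L)
  dots_v <- rowSums(nr[, -1L, , drop = FALSE] * nr[, -nv, , drop = FALSE], dims = 2L)
  if (min(dots_u) < 0 || min(dots_v) < 0) {
    stop("self-intersecting loft: surface orientation flips on the sample grid",
         call. = FALSE)
  }
  invisible(patch)
}

# un-normalized normal by central differences in parameter space
patch_raw_normal <- function(patch, u, v, h = 1e-5) {
  su <- (patch_eval(patch, pmin(u + h, 1), v) -
           patch_eval(patch, pmax(u - h, 0), v))
  sv <- (patch_eval(patch, u, pmin(v + h, 1)) -
           patch_eval(patch, u, pmax(v - h, 0)))
  cbind(su[, 2] * sv[, 3] - su[, 3] * sv[, 2],
        su[, 3] * sv[, 1] - su[, 1] * sv[, 3],
        su[, 1] * sv[, 2] - su[, 2] * sv[, 1])
}

#' @export
print.undersurface_patch <- function(x, ...) {
  cat(sprintf("<undersurface_patch: %d x %d interpolation grid>\n",
              dim(x$points)[1L], dim(x$points)[2L]))
  invisible(x)
}

#' Unit normal field of an undersurface patch
#' @inheritParams patch_eval
#' @return Matrix n x 3 of unit normals (oriented away from the bone for
#'   the canonical pose, i.e. roughly along +x).
#' @export
patch_normal <- function(patch, u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n)
  v <- rep_len(v, n)
  nr <- patch_raw_normal(patch, u, v)
  nr <- nr / sqrt(rowSums(nr^2))
  # consistent orientation: majority vote against the mean normal
  m <- colMeans(nr)
  if (sum(m * c(1, 0, 0)) < 0) nr <- -nr
  nr
}

#' Sample bone contact points inside the plate footprint
#'
#' Dense contact-region samples between stations, used for fit-deviation
#' evaluation: axial positions strictly between consecutive stations,
#' transverse positions spanning `margin` of the locally interpolated
#' station width.
#'
#' @param grid A `feature_grid` built on a bone surface.
#' @param n_axial,n_transverse Sample counts (default 25 x 20 = 500).
#' @param margin Fraction of the local half-width to span (default 0.9).
#' @return Matrix n x 3 of surface points (mm).
#' @export
sample_contact_points <- function(grid, n_axial = 25L, n_transverse = 20L,
                                  margin = 0.9) {
  st <- grid$stations
  zr <- range(st$z)
  dz <- diff(zr) / (n_axial + 1L)
  z <- seq(zr[1L] + dz, zr[2L] - dz, length.out = n_axial)
  z <- z + dz * 0.123 * sin(seq_along(z)) # keep off the stations themselves
  w_at <- drop(cr_eval(st$z, st$width, z)) # local interpolant, matches the loft
  f <- seq(-margin, margin, length.out = n_transverse)
  out <- matrix(0, n_axial * n_transverse, 3L)
  r <- 1L
  for (i in seq_len(n_axial)) {
    w <- max(w_at[i], 0.1)
    out[r:(r + n_transverse - 1L), ] <-
      surface_point(grid$surface, rep(grid$s_off + z[i], n_transverse), f * w / 2)
    r <- r + n_transverse
  }
  out
}

#' Point-to-undersurface fit deviation
#'
#' Minimum Euclidean distance from every contact point to the patch:
#' damped Gauss-Newton projection in the parameter plane (vectorized over
#' all points), seeded by the nearest point of a dense patch sampling;
#' non-converged points fall back to the dense-sample distance and are
#' flagged.
#'
#' @param patch An `undersurface_patch`.
#' @param points Matrix n x 3 of contact points (mm).
#' @param seed_grid Dense-sampling resolution c(nu, nv) for seeding.
#' @param max_iter Iteration cap per point.
#' @return A `fit_report`: tibble of per-point distances with summary
#'   attributes `max`, `mean`, `rms`, `n`.
#' @export
fit_deviation <- function(patch, points, seed_grid = c(41L, 17L),
                          max_iter = 100L) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty contact point set", call. = FALSE)
  n <- nrow(points)
  nu <- seed_grid[1L]
  nv <- seed_grid[2L]
  uq <- rep(seq(0, 1, length.out = nu), times = nv)
  vq <- rep(seq(0, 1, length.out = nv), each = nu)
  dense <- patch_eval(patch, uq, vq)
  d2 <- outer(rowSums(points^2), rowSums(dense^2), "+") - 2 * points %*% t(dense)
  seed_idx <- max.col(-d2)
  seed_dist <- sqrt(pmax(d2[cbind(seq_len(n), seed_idx)], 0))
  u <- uq[seed_idx]
  v <- vq[seed_idx]
  h <- 1e-5
  active <- rep(TRUE, n)
  iters <- integer(n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    ia <- which(active)
    ua <- u[ia]
    va <- v[ia]
    s0 <- patch_eval(patch, ua, va)
    ju <- (patch_eval(patch, pmin(ua + h, 1), va) -
             patch_eval(patch, pmax(ua - h, 0), va)) /
      (pmin(ua + h, 1) - pmax(ua - h, 0))
    jv <- (patch_eval(patch, ua, pmin(va + h, 1)) -
             patch_eval(patch, ua, pmax(va - h, 0))) /
      (pmin(va + h, 1) - pmax(va - h, 0))
    r <- s0 - points[ia, , drop = FALSE]
    g1 <- rowSums(ju * r)
    g2 <- rowSums(jv * r)
    a11 <- rowSums(ju * ju)
    a12 <- rowSums(ju * jv)
    a22 <- rowSums(jv * jv)
    det <- pmax(a11 * a22 - a12^2, 1e-18)
    su <- (a22 * g1 - a12 * g2) / det
    sv <- (a11 * g2 - a12 * g1) / det
    un <- pmin(pmax(ua - su, 0), 1)
    vn <- pmin(pmax(va - sv, 0), 1)
    moved <- abs(un - ua) + abs(vn - va)
    u[ia] <- un
    v[ia] <- vn
    iters[ia] <- it
    active[ia] <- moved > 1e-12
  }
  flagged <- active
  proj <- patch_eval(patch, u, v)
  dist <- sqrt(rowSums((proj - points)^2))
  # projection can only improve on the dense seed
  dist <- pmin(dist, seed_dist)
  out <- tibble::tibble(point = seq_len(n), distance = dist, flagged = flagged)
  structure(out,
            class = c("fit_report", class(out)),
            max = max(dist), mean = mean(dist),
            rms = sqrt(mean(dist^2)), n = length(dist))
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "<fit_report: n = %d, max %.4f mm, mean %.4f mm, RMS %.4f mm%s>\n",
    attr(x, "n"), attr(x, "max"), attr(x, "mean"), attr(x, "rms"),
    if (any(x$flagged)) sprintf(", %d flagged", sum(x$flagged)) else ""
  ))
  invisible(x)
}

#' Summary row of a fit report
#' @param x A `fit_report`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `max`, `mean`, `rms`.
#' @export
glance.fit_report <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), max = attr(x, "max"),
                 mean = attr(x, "mean"), rms = attr(x, "rms"))
}

#' Histogram of fit deviations
#' @param object A `fit_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fit_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = attr(object, "max"),
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "point-to-undersurface distance (mm)", y = "count")
}

#' Fit report as JSON
#' @param report A `fit_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(report, path) {
  jsonlite::write_json(
    list(n = attr(report, "n"), max = attr(report, "max"),
         mean = attr(report, "mean"), rms = attr(report, "rms"),
         distances = report$distance, flagged = report$flagged),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
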