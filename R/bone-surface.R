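#' Synthetic femoral contact surface
#'
#' A smooth parametric proxy for the lateral face of a femur: a generalized
#' cylinder of arc length `H_fs` and radius `D_fs / 2`, uniformly bowed in
#' the coronal plane by a total bend of `180 - A_fs` degrees (apex at
#' mid-shaft, the lateral `+x` side convex), with a greater-trochanter bump
#' rising to height `H_t1` at the proximal end. The bump is a quintic
#' smoothstep in the axial direction (compact support of extent
#' `0.55 * L_t`, so the distal shaft is an exact circular cylinder) and a
#' Gaussian in azimuth whose spread is set by the medial trochanter offset
#' (`sigma_phi = H_t2 / (D_fs / 2)`). Coordinates in mm, bone axis near
#' `+z`, lateral `+x`.
#'
#' @param params Named numeric vector holding at least `D_fs`, `H_fs`,
#'   `A_fs`, `H_t1`, `H_t2`, `L_t` (defaults: the reference means).
#' @param resolution Number of axial rings of the triangulated mesh
#'   (>= 8; azimuthal segments scale with it).
#' @return A `bone_surface` object: generating parameters, analytic
#'   evaluators, a triangle mesh (`$mesh`) and the labeled contact-region
#'   vertex indices (`$contact`).
#' @export
generate_bone_surface <- function(params = mean_femur_parameters(), resolution = 48L) {
  need <- c("D_fs", "H_fs", "A_fs", "H_t1", "H_t2", "L_t")
  if (!all(need %in% names(params))) {
    stop("params must name ", paste(need, collapse = ", "), call. = FALSE)
  }
  p <- as.list(params[need])
  if (resolution < 8L) stop("resolution must be at least 8 rings", call. = FALSE)
  stopifnot(p$D_fs > 0, p$H_fs > 0, p$H_t1 >= 0, p$L_t > 0)
  if (p$A_fs <= 150 || p$A_fs > 180) {
    stop("A_fs must lie in (150, 180] degrees", call. = FALSE)
  }
  obj <- structure(
    list(
      params = unlist(p),
      length = p$H_fs,
      radius = p$D_fs / 2,
      bend = (180 - p$A_fs) * pi / 180,
      bump_height = p$H_t1,
      bump_start = p$H_fs - 0.55 * p$L_t,
      sigma_phi = p$H_t2 / (p$D_fs / 2),
      contact_halfwidth = 1.4 # rad, lateral band labeled as contact region
    ),
    class = c("bone_surface", "contact_surface")
  )
  nphi <- max(24L, as.integer(resolution / 2) * 2L)
  obj$mesh <- surface_mesh(obj, rings = as.integer(resolution), nphi = nphi)
  obj$contact <- attr(obj$mesh, "contact")
  obj
}

# quintic smoothstep, C2 at both ends
smoothstep5 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (10 + x * (-15 + 6 * x))
}

# axis of the bowed shaft at arc length s (vectorized); returns list with
# point (n x 3), tangent, lateral in-plane normal
bone_axis <- function(surface, s) {
  delta <- surface$bend
  h <- surface$length
  if (delta < 1e-12) {
    pt <- cbind(0, 0, s)
    tg <- cbind(0, 0, rep(1, length(s)))
    nl <- cbind(rep(1, length(s)), 0, 0)
    return(list(point = pt, tangent = tg, lateral = nl))
  }
  b <- delta / h
  a <- delta / 2
  theta <- a - b * s
  pt <- cbind((cos(theta) - cos(a)) / b, 0, (sin(a) - sin(theta)) / b)
  tg <- cbind(sin(theta), 0, cos(theta))
  nl <- cbind(cos(theta), 0, -sin(theta))
  list(point = pt, tangent = tg, lateral = nl)
}

# local radius of the cross-section at (s, phi), vectorized
bone_radius <- function(surface, s, phi) {
  n <- max(length(s), length(phi))
  s <- rep_len(s, n)
  phi <- rep_len(phi, n)
  b <- surface$bump_height
  if (b == 0) return(rep(surface$radius, n))
  axial <- smoothstep5((s - surface$bump_start) /
                         (surface$length - surface$bump_start))
  surface$radius + b * axial * exp(-phi^2 / (2 * surface$sigma_phi^2))
}

#' Evaluate a contact surface
#'
#' `surface_point()` returns 3D points; for a bone surface `t` is the
#' transverse arc-length offset from the lateral apex line (mm), for a plane
#' it is the in-plane transverse coordinate.
#'
#' @param surface A `contact_surface` (bone or plane).
#' @param s Axial position(s), mm, in `[0, surface_length(surface)]`.
#' @param t Transverse arc offset(s), mm (recycled against `s`).
#' @return Matrix n x 3 of points (mm).
#' @export
surface_point <- function(surface, s, t) UseMethod("surface_point")

#' @export
surface_point.bone_surface <- function(surface, s, t) {
  n <- max(length(s), length(t))
  s <- rep_len(s, n)
  t <- rep_len(t, n)
  phi <- vapply(seq_len(n), function(i) arc_to_phi(surface, s[i], t[i]), 0)
  ax <- bone_axis(surface, s)
  rho <- bone_radius(surface, s, phi)
  ax$point + rho * (cos(phi) * ax$lateral + sin(phi) * cbind(0, 1, 0)[rep(1, n), , drop = FALSE])
}

# invert transverse arc length -> azimuth at fixed s (scalar)
arc_to_phi <- function(surface, s, t) {
  if (abs(t) < 1e-14) return(0)
  grid <- seq(0, 2.6, length.out = 261L)
  rho <- bone_radius(surface, rep(s, length(grid)), grid)
  drho <- c(diff(rho) / diff(grid), 0)
  ds <- sqrt(rho^2 + drho^2)
  arc <- cumsum(c(0, (ds[-length(ds)] + ds[-1]) / 2 * diff(grid)))
  if (abs(t) > max(arc)) {
    stop("transverse offset exceeds the modeled azimuthal range", call. = FALSE)
  }
  sign(t) * stats::approx(arc, grid, xout = abs(t), ties = "ordered")$y
}

#' Axial extent (arc length) of a contact surface
#' @param surface A `contact_surface`.
#' @return Length in mm.
#' @export
surface_length <- function(surface) UseMethod("surface_length")

#' @export
surface_length.contact_surface <- function(surface) surface$length

#' Outward unit normal of a contact surface
#' @inheritParams surface_point
#' @return Matrix n x 3 of unit normals.
#' @export
surface_normal <- function(surface, s, t) UseMethod("surface_normal")

#' @export
surface_normal.contact_surface <- function(surface, s, t) {
  n <- max(length(s), length(t))
  s <- rep_len(s, n)
  t <- rep_len(t, n)
  h <- 1e-4
  du <- (surface_point(surface, s + h, t) - surface_point(surface, s - h, t)) / (2 * h)
  dv <- (surface_point(surface, s, t + h) - surface_point(surface, s, t - h)) / (2 * h)
  nr <- cbind(
    du[, 2] * dv[, 3] - du[, 3] * dv[, 2],
    du[, 3] * dv[, 1] - du[, 1] * dv[, 3],
    du[, 1] * dv[, 2] - du[, 2] * dv[, 1]
  )
  nr <- nr / sqrt(rowSums(nr^2))
  # orient outward (away from the axis)
  ax <- bone_axis_or_plane(surface, s)
  flip <- rowSums(nr * (surface_point(surface, s, t) - ax)) < 0
  nr[flip, ] <- -nr[flip, , drop = FALSE]
  nr
}

bone_axis_or_plane <- function(surface, s) UseMethod("bone_axis_or_plane")

#' @export
bone_axis_or_plane.bone_surface <- function(surface, s) bone_axis(surface, s)$point

#' @export
bone_axis_or_plane.plane_surface <- function(surface, s) {
  cbind(-1, 0, s) # a point behind the plane so +x is outward
}

#' Flat contact surface
#'
#' An x = 0 plane parameterized by `(s, t) -> (0, t, s)`, used for template
#' construction and as the degenerate bone in tests.
#'
#' @param length Axial extent, mm.
#' @return A `plane_surface` object.
#' @export
plane_surface <- function(length = 400) {
  structure(list(length = length),
            class = c("plane_surface", "contact_surface"))
}

#' @export
surface_point.plane_surface <- function(surface, s, t) {
  n <- max(length(s), length(t))
  cbind(0, rep_len(t, n), rep_len(s, n))
}

# Triangulated mesh of a bone surface; deterministic in its inputs.
surface_mesh <- function(surface, rings = 48L, nphi = 32L) {
  s <- seq(0, surface$length, length.out = rings)
  phi <- seq(-pi, pi, length.out = nphi + 1L)[-(nphi + 1L)]
  grid <- expand.grid(phi = phi, s = s)
  ax <- bone_axis(surface, grid$s)
  rho <- bone_radius(surface, grid$s, grid$phi)
  v <- ax$point + rho * (cos(grid$phi) * ax$lateral +
                           sin(grid$phi) * cbind(0, 1, 0)[rep(1, nrow(grid)), ])
  idx <- function(i, j) (i - 1L) * nphi + ((j - 1L) %% nphi) + 1L
  faces <- vector("list", (rings - 1L) * nphi)
  f <- 1L
  for (i in seq_len(rings - 1L)) {
    for (j in seq_len(nphi)) {
      a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      faces[[f]] <- rbind(c(a, b, d), c(a, d, cc))
      f <- f + 1L
    }
  }
  mesh <- tri_mesh(v, do.call(rbind, faces))
  attr(mesh, "contact") <- which(abs(grid$phi) <= surface$contact_halfwidth)
  mesh
}
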