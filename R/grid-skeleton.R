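#' Build the feature-point grid of a plate on a contact surface
#'
#' Lays out the 11 transverse stations of the eagle-shaped plate along the
#' contact surface and samples each station's profile points across its
#' local width. Stations (tail tip, two tail stations `w0`/`w1`, the neck
#' junction `w2`, six head stations `w3..w8`, head tip) span the axial
#' extent `l1 + l2` exactly; widths are measured as arc length along the
#' surface (on a plane, arc equals chord).
#'
#' Two height modes: `"measured"` (any curved bone surface): profile points
#' are exact surface samples and the attained apex heights are recorded;
#' `"parametric"` (plane/template mode): the semantic bump heights `h_i`
#' lift each profile apex off the surface with a smooth transverse bump.
#' `"auto"` picks `measured` for a bone surface and `parametric` for a
#' plane.
#'
#' @param params A `semantic_parameters` object.
#' @param surface A `contact_surface` ([generate_bone_surface()] or
#'   [plane_surface()]).
#' @param n_profile Profile points per station (odd, >= 5).
#' @param heights `"auto"`, `"measured"` or `"parametric"`.
#' @return A `feature_grid`: stations tibble, point array
#'   `[station, profile, xyz]`, the surface and the parameters.
#' @export
build_feature_points <- function(params, surface, n_profile = 9L,
                                 heights = c("auto", "measured", "parametric")) {
  heights <- match.arg(heights)
  stopifnot(inherits(params, "semantic_parameters"),
            inherits(surface, "contact_surface"),
            n_profile >= 5L, n_profile %% 2L == 1L)
  if (heights == "auto") {
    heights <- if (inherits(surface, "plane_surface")) "parametric" else "measured"
  }
  l1 <- params$l1
  l2 <- params$l2
  L <- params$L
  s_len <- surface_length(surface)
  if (L > s_len) {
    stop(sprintf("plate footprint exceeds contact region by %.2f mm", L - s_len),
         call. = FALSE)
  }
  s_off <- (s_len - L) / 2
  stations <- tibble::tibble(
    station = 1:11,
    z = c(0, l1 / 3, 2 * l1 / 3, l1, l1 + (1:6) * l2 / 7, L),
    width = c(0.45 * params$w[["w0"]], params$w[["w0"]], params$w[["w1"]],
              params$w[["w2"]], params$w[["w3"]], params$w[["w4"]],
              params$w[["w5"]], params$w[["w6"]], params$w[["w7"]],
              params$w[["w8"]], 0.5 * params$w[["w8"]]),
    height = c(0, params$h[["h0"]], params$h[["h1"]], params$h[["h2"]],
               params$h[["h3"]], params$h[["h4"]], params$h[["h5"]],
               params$h[["h6"]], params$h[["h7"]], params$h[["h8"]], 0),
    costal = c(NA, "C10", "C11", "C9", "C3", "C4", "C5", "C6", "C7", "C8", NA)
  )
  u <- seq(-1, 1, length.out = n_profile)
  pts <- array(NA_real_, dim = c(11L, n_profile, 3L))
  attained <- numeric(11L)
  for (i in 1:11) {
    s <- s_off + stations$z[i]
    t <- u * stations$width[i] / 2
    p <- tryCatch(
      surface_point(surface, rep(s, n_profile), t),
      error = function(e) {
        stop(sprintf("station %d (width %.1f mm) overhangs the contact region: %s",
                     i, stations$width[i], conditionMessage(e)), call. = FALSE)
      }
    )
    if (heights == "parametric" && stations$height[i] > 0) {
      nr <- surface_normal(surface, rep(s, n_profile), t)
      p <- p + stations$height[i] * cos(pi * u / 2)^2 * nr
    }
    pts[i, , ] <- p
    mid <- (p[1L, ] + p[n_profile, ]) / 2
    attained[i] <- sqrt(sum((p[(n_profile + 1L) / 2, ] - mid)^2))
  }
  stations$height_attained <- attained
  structure(
    list(stations = stations, points = pts, params = params,
         surface = surface, s_off = s_off, mode = heights,
         n_profile = n_profile),
    class = "feature_grid"
  )
}

#' @export
print.feature_grid <- function(x, ...) {
  cat(sprintf("<feature_grid: 11 stations x %d profile points, %s heights, extent %.1f mm>\n",
              x$n_profile, x$mode, max(x$stations$z)))
  invisible(x)
}

#' Axial extent of a feature grid
#' @param grid A `feature_grid`.
#' @return Extent in mm (distance between first and last station).
#' @export
grid_extent <- function(grid) max(grid$stations$z) - min(grid$stations$z)

#' Build the twelve-curve plate skeleton from a feature grid
#'
#' Costal curves `C3..C8` interpolate the six head-station profiles, `C9`
#' the neck-junction profile and `C10`/`C11` the two tail-station profiles;
#' ridge curves `C1` (tail) and `C2` (head) interpolate the station apexes
#' and meet end-to-end at the neck junction; the closed boundary `C0` runs
#' through the tail apex, all left profile ends, the head apex and all
#' right profile ends. The computed topology matrix of the result equals
#' the published eagle-plate adjacency matrix.
#'
#' @param grid A `feature_grid` with 11 stations.
#' @return A `skeleton_curves` object: named list of 12 `feature_curve`s
#'   (`C0..C11`) with the grid attached.
#' @export
build_skeleton <- function(grid) {
  stopifnot(inherits(grid, "feature_grid"))
  if (nrow(grid$stations) < 11L) {
    stop("skeleton construction needs the full set of 11 stations", call. = FALSE)
  }
  pts <- grid$points
  np <- grid$n_profile
  apex <- (np + 1L) / 2L
  apexes <- pts[, apex, , drop = FALSE]
  dim(apexes) <- c(dim(pts)[1L], 3L)
  profile <- function(i) matrix(pts[i, , ], ncol = 3L)
  curves <- list(
    C0 = feature_curve(rbind(
      apexes[1L, , drop = FALSE],       # tail apex (C1 terminus)
      matrix(pts[, 1L, ], ncol = 3L),   # left profile ends, tail -> head
      apexes[11L, , drop = FALSE],      # head apex (C2 terminus)
      matrix(pts[11:1, np, ], ncol = 3L) # right profile ends, head -> tail
    ), kind = "boundary", id = "C0"),
    C1 = feature_curve(apexes[1:4, ], id = "C1"),
    C2 = feature_curve(apexes[4:11, ], id = "C2"),
    C3 = feature_curve(profile(5L), id = "C3"),
    C4 = feature_curve(profile(6L), id = "C4"),
    C5 = feature_curve(profile(7L), id = "C5"),
    C6 = feature_curve(profile(8L), id = "C6"),
    C7 = feature_curve(profile(9L), id = "C7"),
    C8 = feature_curve(profile(10L), id = "C8"),
    C9 = feature_curve(profile(4L), id = "C9"),
    C10 = feature_curve(profile(2L), id = "C10"),
    C11 = feature_curve(profile(3L), id = "C11")
  )
  structure(curves, class = "skeleton_curves", grid = grid)
}

#' @export
print.skeleton_curves <- function(x, ...) {
  cat("<skeleton_curves: C0 boundary + C1/C2 ridges + C3..C11 costals>\n")
  invisible(x)
}
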