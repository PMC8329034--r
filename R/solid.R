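#' Extrude the plate solid from the undersurface
#'
#' Offsets the lofted undersurface along its unit normals by a thickness
#' field blending tail thickness `t1` into head thickness `t2` with a
#' quintic smoothstep over the neck region (10% of the plate length,
#' centered at the tail/head junction), stitches the side walls and returns
#' a watertight triangle shell plus the solid specification.
#'
#' @param patch An `undersurface_patch`.
#' @param params The `semantic_parameters` of the plate (thickness, holes).
#' @param n_u,n_v Sampling resolution of the shell.
#' @return A `plate_solid`: list with `patch`, `params`, `mesh`,
#'   `thickness` sampler and an empty hole table (see [place_holes()]).
#' @export
extrude_solid <- function(patch, params, n_u = 41L, n_v = 17L) {
  stopifnot(params$t1 > 0, params$t2 > 0)
  grid <- patch$grid
  zfun <- stats::splinefun(patch$u, grid$stations$z, method = "fmm")
  l1 <- params$l1
  L <- params$L
  tfun <- function(u) {
    z <- zfun(u)
    params$t1 + (params$t2 - params$t1) *
      smoothstep5((z - (l1 - 0.05 * L)) / (0.1 * L))
  }
  uq <- seq(0, 1, length.out = n_u)
  vq <- seq(0, 1, length.out = n_v)
  q <- expand.grid(u = uq, v = vq) # u fastest
  bottom <- patch_eval(patch, q$u, q$v)
  nr <- patch_normal(patch, q$u, q$v)
  th <- tfun(q$u)
  top <- bottom + nr * th
  # local curvature guard: offsetting must not fold the top sheet
  idx <- function(i, j) (j - 1L) * n_u + i
  fold <- FALSE
  for (j in seq_len(n_v)) {
    rows <- idx(seq_len(n_u), j)
    db <- diff(bottom[rows, , drop = FALSE])
    dt <- diff(top[rows, , drop = FALSE])
    if (any(rowSums(db * dt) < 0)) fold <- TRUE
  }
  if (fold) {
    stop("offset self-intersection: thickness exceeds local curvature radius",
         call. = FALSE)
  }
  verts <- rbind(bottom, top)
  ntop <- nrow(bottom)
  faces <- list()
  add <- function(a, b, cc) faces[[length(faces) + 1L]] <<- c(a, b, cc)
  for (j in seq_len(n_v - 1L)) {
    for (i in seq_len(n_u - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
      # bottom sheet: outward is -normal
      add(a, cc, b); add(b, cc, d)
      # top sheet: outward is +normal
      add(a + ntop, b + ntop, cc + ntop); add(b + ntop, d + ntop, cc + ntop)
    }
  }
  wall <- function(rim) { # rim: bottom-sheet indices ordered along the wall
    for (k in seq_len(length(rim) - 1L)) {
      a <- rim[k]; b <- rim[k + 1L]
      add(a, b, a + ntop); add(b, b + ntop, a + ntop)
    }
  }
  wall(idx(seq_len(n_u), 1L))                      # v = 0 edge
  wall(idx(n_u, seq_len(n_v)))                     # u = 1 edge
  wall(idx(rev(seq_len(n_u)), n_v))                # v = 1 edge, reversed
  wall(idx(1L, rev(seq_len(n_v))))                 # u = 0 edge, reversed
  mesh <- tri_mesh(verts, do.call(rbind, faces))
  structure(
    list(patch = patch, params = params, mesh = mesh, thickness = tfun,
         holes = tibble::tibble(
           id = character(), kind = character(), diameter = double(),
           u = double(), v = double(), arc = double(),
           x = double(), y = double(), z = double(),
           ax = double(), ay = double(), az = double()
         )),
    class = "plate_solid"
  )
}

#' @export
print.plate_solid <- function(x, ...) {
  cat(sprintf("<plate_solid: %d vertices, %d faces, %d holes>\n",
              nrow(x$mesh$vertices), nrow(x$mesh$faces), nrow(x$holes)))
  invisible(x)
}

#' Place screw holes on a plate solid
#'
#' Tail holes of diameter `d1` are centered on the tail ridge with clear
#' rim-to-rim spacing `s1` (centers `s1 + d1` apart in arc length), as many
#' as fit in the tail length `l1`
#' (`floor((l1 - d1) / (s1 + d1)) + 1`); head holes of diameters `d2` and
#' `d3` sit at the two central head stations (`w4`, `w6`). Hole axes are
#' the local surface normals. Holes are recorded as specification metadata;
#' the shell mesh is not boolean-subtracted.
#'
#' @param solid A `plate_solid`.
#' @param params Semantic parameters (defaults to the solid's own).
#' @return The solid with a populated hole table.
#' @export
place_holes <- function(solid, params = solid$params) {
  stopifnot(params$s1 > 0)
  patch <- solid$patch
  grid <- patch$grid
  tail_widths <- grid$stations$width[2:4]
  if (params$d1 >= min(tail_widths)) {
    stop("tail hole diameter d1 exceeds the minimum tail width", call. = FALSE)
  }
  v_apex <- patch$v[(grid$n_profile + 1L) / 2L]
  # arc length along the apex (ridge) line as a function of u
  us <- seq(0, 1, length.out = 801L)
  apexline <- patch_eval(patch, us, v_apex)
  seg <- sqrt(rowSums(diff(apexline)^2))
  arc <- c(0, cumsum(seg))
  l1 <- params$l1
  count <- floor((l1 - params$d1) / (params$s1 + params$d1)) + 1
  if (count < 1) stop("tail too short for a single hole", call. = FALSE)
  centers_arc <- params$d1 / 2 + (seq_len(count) - 1L) * (params$s1 + params$d1)
  u_tail <- stats::approx(arc, us, xout = centers_arc, ties = "ordered")$y
  u_head <- patch$u[c(6L, 8L)] # stations carrying w4 and w6
  hu <- c(u_tail, u_head)
  hv <- rep(v_apex, length(hu))
  centers <- patch_eval(patch, hu, hv)
  axes <- patch_normal(patch, hu, hv)
  solid$holes <- tibble::tibble(
    id = c(sprintf("tail_%02d", seq_len(count)), "head_1", "head_2"),
    kind = c(rep("tail", count), "head", "head"),
    diameter = c(rep(params$d1, count), params$d2, params$d3),
    u = hu, v = hv,
    arc = c(centers_arc, NA, NA),
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    ax = axes[, 1], ay = axes[, 2], az = axes[, 3]
  )
  solid
}

#' Plate solid specification as JSON
#'
#' @param solid A `plate_solid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solid_json <- function(solid, path) {
  p <- solid$params
  jsonlite::write_json(
    list(
      units = "mm",
      semantic = list(L = p$L, W = p$W, l1 = p$l1, l2 = p$l2,
                      w = as.list(p$w), h = as.list(p$h),
                      t1 = p$t1, t2 = p$t2,
                      d1 = p$d1, d2 = p$d2, d3 = p$d3, s1 = p$s1),
      holes = solid$holes,
      mesh = list(vertices = nrow(solid$mesh$vertices),
                  faces = nrow(solid$mesh$faces))
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' End-to-end plate design from femoral parameters
#'
#' Runs the full pipeline for one subject: synthetic bone surface,
#' semantic-parameter derivation, feature grid, skeleton, lofted
#' undersurface, extruded solid with hole layout, and fit-deviation
#' evaluation on dense contact samples.
#'
#' @param bone Named femoral parameter vector (29 schema entries).
#' @param resolution Bone mesh resolution (rings).
#' @param n_contact Approximate number of contact samples for the fit
#'   report (default 500).
#' @param coeffs Mapping coefficients.
#' @return A `plate_design`: list with `bone`, `surface`, `semantic`,
#'   `grid`, `skeleton`, `patch`, `solid`, `fit`.
#' @export
design_plate <- function(bone, resolution = 48L, n_contact = 500L,
                         coeffs = default_mapping_coefficients()) {
  surface <- generate_bone_surface(bone, resolution = resolution)
  semantic <- derive_semantic_parameters(bone, coeffs)
  grid <- build_feature_points(semantic, surface)
  skel <- build_skeleton(grid)
  patch <- loft_undersurface(skel)
  solid <- place_holes(extrude_solid(patch, semantic))
  n_tr <- max(4L, round(sqrt(n_contact / 1.25)))
  n_ax <- max(4L, round(n_contact / n_tr))
  contact <- sample_contact_points(grid, n_axial = n_ax, n_transverse = n_tr)
  fit <- fit_deviation(patch, contact)
  structure(
    list(bone = bone, surface = surface, semantic = semantic, grid = grid,
         skeleton = skel, patch = patch, solid = solid, fit = fit),
    class = "plate_design"
  )
}

#' @export
print.plate_design <- function(x, ...) {
  cat(sprintf("<plate_design: L = %.1f mm, max fit deviation %.4f mm>\n",
              x$semantic$L, attr(x$fit, "max")))
  invisible(x)
}
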