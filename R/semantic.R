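#' Semantic parameter set of the eagle-shaped plate
#'
#' The plate-level design parameters with their inheritance hierarchy: total
#' length `L` splits into tail length `l1` and head length `l2`; total width
#' `W` bounds the local station widths `w0..w8`; `h0..h8` are local bump
#' heights; `t1`/`t2` are tail/head thickness; `d1..d3` are screw-hole
#' diameters and `s1` the clear spacing between tail holes. All mm.
#'
#' @param l1,l2 Tail / head length (mm); `L = l1 + l2`.
#' @param W Total width (mm), defaults to the largest local width.
#' @param w Named or plain numeric vector of 9 local widths `w0..w8`.
#' @param h Numeric vector of 9 local bump heights `h0..h8` (>= 0).
#' @param t1,t2 Tail / head thickness (mm).
#' @param d1,d2,d3 Hole diameters (mm).
#' @param s1 Clear spacing between consecutive tail-hole rims (mm).
#' @return A `semantic_parameters` object (named list).
#' @export
semantic_parameters <- function(l1, l2, w, h, W = max(w),
                                t1 = 3, t2 = 3,
                                d1 = 7, d2 = 5, d3 = 5, s1 = 6) {
  stopifnot(length(w) == 9L, length(h) == 9L)
  w <- stats::setNames(as.numeric(w), paste0("w", 0:8))
  h <- stats::setNames(as.numeric(h), paste0("h", 0:8))
  out <- structure(
    list(L = l1 + l2, W = W, l1 = l1, l2 = l2, w = w, h = h,
         t1 = t1, t2 = t2, d1 = d1, d2 = d2, d3 = d3, s1 = s1),
    class = "semantic_parameters"
  )
  viol <- check_dimension_constraints(out, stats = NULL)
  hier <- viol[viol$kind == "hierarchy", , drop = FALSE]
  if (nrow(hier) > 0L) {
    stop("invalid semantic parameters: ",
         paste(hier$parameter, hier$rule, collapse = "; "), call. = FALSE)
  }
  out
}

#' @export
print.semantic_parameters <- function(x, ...) {
  cat(sprintf(
    "<semantic_parameters: L = %.1f (l1 %.1f + l2 %.1f), W = %.1f mm>\n",
    x$L, x$l1, x$l2, x$W
  ))
  cat("  w:", paste(sprintf("%.1f", x$w), collapse = " "), "\n")
  cat("  h:", paste(sprintf("%.1f", x$h), collapse = " "), "\n")
  cat(sprintf("  t1 %.1f t2 %.1f | d %g/%g/%g s1 %g\n",
              x$t1, x$t2, x$d1, x$d2, x$d3, x$s1))
  invisible(x)
}

#' Published plate parameter presets
#'
#' The three published eagle-shaped plate instances. Only `w0, w1, w2, w5,
#' w7` and `h2..h8` (plus lengths, thickness and hole parameters) are
#' printed; the remaining widths (`w3, w4, w6, w8`) and the tail heights
#' (`h0, h1`) are synthetic fill values interpolated smoothly between
#' printed neighbours.
#'
#' @param which `"A"`, `"B"` or `"C"`.
#' @return A `semantic_parameters` object.
#' @export
plate_preset <- function(which = c("A", "B", "C")) {
  which <- match.arg(which)
  spec <- switch(which,
    A = list(l1 = 229, l2 = 39,
             w = c(12, 14, 16, 20, 25, 29, 22, 13, 12),
             h = c(0.4, 0.4, 1.6, 2.4, 7.9, 8.3, 5.2, 0.8, 0.7)),
    B = list(l1 = 204, l2 = 44,
             w = c(12, 14, 15, 18, 22, 25, 19, 13, 12),
             h = c(0.4, 0.4, 1.5, 2.2, 7.2, 8.6, 5.3, 1.0, 0.9)),
    C = list(l1 = 248, l2 = 40,
             w = c(12, 14, 17, 21, 27, 33, 24, 14, 13),
             h = c(0.4, 0.4, 1.4, 2.8, 7.3, 8.0, 4.7, 1.2, 1.3))
  )
  semantic_parameters(l1 = spec$l1, l2 = spec$l2, w = spec$w, h = spec$h)
}

#' Default bone-to-plate derivation coefficients
#'
#' Calibrated once so that the reference mean femur yields the published
#' Plate A: `alpha_L = 268 / 420.072` (plate length per femur length),
#' `alpha_W = 29 / 25.94` (width per shaft coronal diameter),
#' `beta = 39 / 65.86` (head length per trochanter length), local width
#' fractions `cw_i = w_i^A / W^A`, local height fractions
#' `ch_i = h_i^A / H_t1` at the reference mean trochanter. All coefficients
#' are user-overridable.
#'
#' @return Named list of coefficients.
#' @export
default_mapping_coefficients <- function() {
  a <- plate_preset("A")
  mu <- mean_femur_parameters()
  list(
    alpha_L = a$L / mu[["H_f"]],
    alpha_W = a$W / mu[["D_fs"]],
    beta = a$l2 / mu[["L_t"]],
    cw = a$w / a$W,
    ch = a$h / mu[["H_t1"]],
    t1 = a$t1, t2 = a$t2, d1 = a$d1, d2 = a$d2, d3 = a$d3, s1 = a$s1
  )
}

# size factor driving local widths: a positive average of reconstructable
# proximal and distal size parameters, equal to 1 at the reference mean
width_size_factor <- function(bone, mu) {
  prox <- mean(c(bone[["D_fh"]] / mu[["D_fh"]],
                 bone[["D_fn"]] / mu[["D_fn"]],
                 bone[["L_t"]] / mu[["L_t"]]))
  dist <- mean(c(bone[["L_df"]] / mu[["L_df"]],
                 bone[["L_m"]] / mu[["L_m"]],
                 bone[["L_l"]] / mu[["L_l"]]))
  (prox + dist) / 2
}

#' Derive plate semantic parameters from femoral parameters
#'
#' The primary bone-to-plate mapping: plate length from femur length
#' (`L = alpha_L * H_f`), width from shaft coronal diameter
#' (`W = alpha_W * D_fs`), head length from trochanter length
#' (`l2 = beta * L_t`, `l1 = L - l2`), local widths from the width
#' fractions scaled by a proximal+distal size factor, and local heights
#' from the height fractions scaled by the trochanter bump height `H_t1`.
#' Derived parameters violating their dimension constraints raise an error
#' listing the violations.
#'
#' @param bone Named femoral parameter vector (schema names; needs at least
#'   `H_f`, `D_fs`, `L_t`, `H_t1` and the size-factor parameters).
#' @param coeffs Coefficient list, see [default_mapping_coefficients()].
#' @param stats Reference stats used for the constraint ranges.
#' @return A `semantic_parameters` object.
#' @export
derive_semantic_parameters <- function(bone, coeffs = default_mapping_coefficients(),
                                       stats = femur_reference_stats()) {
  bone <- unlist(bone)
  mu <- mean_femur_parameters()
  for (nm in c("H_f", "D_fs", "L_t", "H_t1")) {
    if (!is.finite(bone[[nm]]) || bone[[nm]] <= 0) {
      stop("bone parameter ", nm, " must be positive", call. = FALSE)
    }
  }
  L <- coeffs$alpha_L * bone[["H_f"]]
  W <- coeffs$alpha_W * bone[["D_fs"]]
  l2 <- coeffs$beta * bone[["L_t"]]
  l1 <- L - l2
  g <- width_size_factor(bone, mu)
  w <- coeffs$cw * W * g
  h <- coeffs$ch * bone[["H_t1"]]
  out <- structure(
    list(L = L, W = max(W, max(w)), l1 = l1, l2 = l2,
         w = stats::setNames(w, paste0("w", 0:8)),
         h = stats::setNames(h, paste0("h", 0:8)),
         t1 = coeffs$t1, t2 = coeffs$t2,
         d1 = coeffs$d1, d2 = coeffs$d2, d3 = coeffs$d3, s1 = coeffs$s1),
    class = "semantic_parameters"
  )
  viol <- check_dimension_constraints(out, stats = stats, coeffs = coeffs)
  if (nrow(viol) > 0L) {
    stop("derived semantic parameters violate constraints: ",
         paste(sprintf("%s (%s)", viol$parameter, viol$rule), collapse = "; "),
         call. = FALSE)
  }
  out
}

#' Check dimension constraints of a semantic parameter set
#'
#' Two layers: exact hierarchy identities (`L = l1 + l2`, `W >= max(w_i)`,
#' positivity, `h_i >= 0`) and, when reference statistics are supplied,
#' admissible ranges for the bone-derived parameters set to the value
#' derived at the reference mean +/- 3 linearly propagated SDs.
#'
#' @param params A `semantic_parameters` object.
#' @param stats Reference stats tibble (or `NULL` to check hierarchy only).
#' @param coeffs Coefficients used for range propagation.
#' @return Tibble of violations (`parameter`, `kind`, `rule`, `value`);
#'   zero rows when valid. Violations are data, not errors.
#' @export
check_dimension_constraints <- function(params, stats = femur_reference_stats(),
                                        coeffs = default_mapping_coefficients()) {
  v <- list()
  bad <- function(parameter, kind, rule, value) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      parameter = parameter, kind = kind, rule = rule, value = value
    )
  }
  if (abs(params$L - (params$l1 + params$l2)) > 1e-9) {
    bad("L", "hierarchy", "L = l1 + l2 violated", params$L)
  }
  over_w <- names(params$w)[params$w > params$W + 1e-9]
  for (nm in over_w) bad(nm, "hierarchy", "exceeds total width W", params$w[[nm]])
  neg_h <- names(params$h)[params$h < 0]
  for (nm in neg_h) bad(nm, "hierarchy", "bump height negative", params$h[[nm]])
  for (nm in c("L", "W", "l1", "l2", "t1", "t2", "d1", "d2", "d3", "s1")) {
    if (params[[nm]] <= 0) bad(nm, "hierarchy", "must be positive", params[[nm]])
  }
  if (any(params$w <= 0)) {
    for (nm in names(params$w)[params$w <= 0]) {
      bad(nm, "hierarchy", "must be positive", params$w[[nm]])
    }
  }
  if (!is.null(stats)) {
    sd_of <- stats::setNames(stats$sd, stats$name)
    mu <- stats::setNames(stats$mean, stats$name)
    range_check <- function(nm, value, center, spread) {
      lo <- center - 3 * spread
      hi <- center + 3 * spread
      if (value < lo - 1e-9 || value > hi + 1e-9) {
        bad(nm, "range",
            sprintf("outside [%.1f, %.1f] mm", lo, hi), value)
      }
    }
    range_check("L", params$L, coeffs$alpha_L * mu[["H_f"]],
                coeffs$alpha_L * sd_of[["H_f"]])
    range_check("W", params$W, coeffs$alpha_W * mu[["D_fs"]],
                coeffs$alpha_W * sd_of[["D_fs"]])
    range_check("l2", params$l2, coeffs$beta * mu[["L_t"]],
                coeffs$beta * sd_of[["L_t"]])
    # size-factor SD, delta method over its six independent drivers
    g_sd <- sqrt(sum((sd_of[c("D_fh", "D_fn", "L_t")] /
                        mu[c("D_fh", "D_fn", "L_t")] / 6)^2) +
                   sum((sd_of[c("L_df", "L_m", "L_l")] /
                          mu[c("L_df", "L_m", "L_l")] / 6)^2))
    w_center <- coeffs$cw * coeffs$alpha_W * mu[["D_fs"]]
    w_sd <- w_center * sqrt((sd_of[["D_fs"]] / mu[["D_fs"]])^2 + g_sd^2)
    for (i in 1:9) {
      range_check(paste0("w", i - 1L), params$w[[i]], w_center[[i]], w_sd[[i]])
    }
    for (i in 1:9) {
      range_check(paste0("h", i - 1L), params$h[[i]],
                  coeffs$ch[[i]] * mu[["H_t1"]], coeffs$ch[[i]] * sd_of[["H_t1"]])
    }
  }
  if (length(v) == 0L) {
    return(tibble::tibble(parameter = character(), kind = character(),
                          rule = character(), value = double()))
  }
  dplyr::bind_rows(v)
}

#' Component mapping from principal-component scores to plate parameters
#'
#' The component mapping augments the primary bone-to-plate mapping with the
#' retained principal components as weights: a subject's score set
#' `P4 = {p1..p4, q1..q7}` is turned back into standardized bone parameters
#' (least-squares reconstruction through the raw loadings), de-standardized
#' with the cohort means/SDs, and run through
#' [derive_semantic_parameters()]. Zero scores reproduce the base
#' (mean-shape) plate exactly. Parameters outside the retained-component
#' span (the shaft block and overall length) stay at their cohort means.
#'
#' @param proximal,distal Raw `loading_matrix` objects (4 x 9 and 7 x 16).
#' @param stats Cohort distribution stats for de-standardization.
#' @param coeffs Derivation coefficients.
#' @return A `component_mapping` object.
#' @export
component_mapping <- function(proximal = proximal_loadings(),
                              distal = distal_loadings(normalize = TRUE),
                              stats = femur_reference_stats(),
                              coeffs = default_mapping_coefficients()) {
  if (is_rotated(proximal) || is_rotated(distal)) {
    stop("component mapping requires raw (unrotated) loadings", call. = FALSE)
  }
  structure(
    list(proximal = proximal, distal = distal, stats = stats, coeffs = coeffs,
         base = derive_semantic_parameters(
           stats::setNames(stats$mean, stats$name), coeffs, stats
         )),
    class = "component_mapping"
  )
}

#' Apply a component mapping to a score set
#'
#' @param scores Numeric vector of length 11: proximal scores `p1..p4`
#'   followed by distal scores `q1..q7`.
#' @param mapping A [component_mapping()].
#' @return A `semantic_parameters` object.
#' @export
apply_component_mapping <- function(scores, mapping) {
  bone <- reconstruct_bone_parameters(scores, mapping)
  derive_semantic_parameters(bone, mapping$coeffs, mapping$stats)
}

#' Reconstruct full femoral parameters from a score set
#'
#' Least-squares reconstruction of the proximal and distal blocks through
#' the raw loadings, de-standardized with the cohort means/SDs; parameters
#' outside the retained-component span (the shaft block and `H_f`) stay at
#' their cohort means.
#'
#' @inheritParams apply_component_mapping
#' @return Named femoral parameter vector over all 29 schema entries.
#' @export
reconstruct_bone_parameters <- function(scores, mapping) {
  stopifnot(inherits(mapping, "component_mapping"))
  kp <- nrow(mapping$proximal)
  kd <- nrow(mapping$distal)
  if (length(scores) != kp + kd) {
    stop(sprintf("scores must have length %d (proximal) + %d (distal)", kp, kd),
         call. = FALSE)
  }
  mu <- stats::setNames(mapping$stats$mean, mapping$stats$name)
  sd <- stats::setNames(mapping$stats$sd, mapping$stats$name)
  bone <- mu # span gaps (shaft block, H_f) stay at the cohort mean
  zp <- reconstruct_parameters(scores[seq_len(kp)], mapping$proximal)
  zd <- reconstruct_parameters(scores[kp + seq_len(kd)], mapping$distal)
  prox <- region_parameters("proximal")
  dist <- region_parameters("distal")
  bone[prox] <- mu[prox] + sd[prox] * zp
  bone[dist] <- mu[dist] + sd[dist] * zd
  bone
}

#' JSON round trip for semantic parameter sets
#'
#' @param params A `semantic_parameters` object.
#' @param path File path.
#' @return `write_semantic_json()` returns `path` invisibly;
#'   `read_semantic_json()` returns a `semantic_parameters` object.
#' @export
write_semantic_json <- function(params, path) {
  jsonlite::write_json(
    list(units = "mm", L = params$L, W = params$W, l1 = params$l1,
         l2 = params$l2, w = as.list(params$w), h = as.list(params$h),
         t1 = params$t1, t2 = params$t2, d1 = params$d1, d2 = params$d2,
         d3 = params$d3, s1 = params$s1),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_semantic_json
#' @export
read_semantic_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  semantic_parameters(
    l1 = x$l1, l2 = x$l2, w = unlist(x$w), h = unlist(x$h), W = x$W,
    t1 = x$t1, t2 = x$t2, d1 = x$d1, d2 = x$d2, d3 = x$d3, s1 = x$s1
  )
}
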