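#' Feature curve of the plate skeleton
#'
#' A feature curve is an ordered 3D point sequence interpolated by a cubic
#' spline (chord-length parameterized). The single boundary curve (`B`) is
#' closed; internal auxiliary curves (`I`) -- ridge and costal curves -- are
#' open.
#'
#' @param points n x 3 numeric matrix (mm), n >= 4, no consecutive
#'   duplicates.
#' @param kind `"boundary"` or `"internal"`.
#' @param id Curve identifier (`"C0"` .. `"C11"` for the shipped template).
#' @return A `feature_curve` object.
#' @export
feature_curve <- function(points, kind = c("internal", "boundary"), id = NULL) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (nrow(points) < 4L) stop("a feature curve needs at least 4 points", call. = FALSE)
  dup <- rowSums((points[-1L, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2) < 1e-20
  if (any(dup)) stop("consecutive duplicate points in curve", call. = FALSE)
  structure(
    list(id = id, kind = kind, points = points, closed = kind == "boundary"),
    class = "feature_curve"
  )
}

#' @export
print.feature_curve <- function(x, ...) {
  cat(sprintf("<feature_curve %s: %s, %d points%s>\n",
              x$id %||% "?", x$kind, nrow(x$points),
              if (x$closed) ", closed" else ""))
  invisible(x)
}

# chord-length parameter values of the control points (closed curves repeat
# the first point at the end)
curve_knots <- function(curve) {
  pts <- curve$points
  if (curve$closed) pts <- rbind(pts, pts[1L, ])
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

#' Evaluate a feature curve at arc-like parameters
#'
#' @param curve A `feature_curve`.
#' @param t Parameter values in `[0, max(curve_knots(curve))]`.
#' @return Matrix length(t) x 3.
#' @export
curve_eval <- function(curve, t) {
  pts <- curve$points
  if (curve$closed) pts <- rbind(pts, pts[1L, ])
  u <- curve_knots(curve)
  method <- if (curve$closed) "periodic" else "fmm"
  out <- vapply(1:3, function(k) {
    stats::splinefun(u, pts[, k], method = method)(t)
  }, numeric(length(t)))
  matrix(out, ncol = 3L)
}

# densified polyline: parameters include the knots themselves so shared
# control points are reproduced exactly
curve_polyline <- function(curve, per_span = 24L) {
  u <- curve_knots(curve)
  t <- sort(unique(c(u, seq(0, max(u), length.out = (length(u) - 1L) * per_span + 1L))))
  list(t = t, pts = curve_eval(curve, t))
}

# minimum distances between all segment pairs of two polylines; returns the
# candidate pairs below `thresh` (segment indices + closest points)
segment_candidates <- function(P, Q, thresh) {
  np <- nrow(P$pts) - 1L
  nq <- nrow(Q$pts) - 1L
  if (np > nq) { # loop over the shorter curve, vectorize over the longer
    sw <- segment_candidates(Q, P, thresh)
    if (is.null(sw)) return(NULL)
    return(tibble::tibble(i = sw$j, j = sw$i, dist = sw$dist,
                          sp = sw$sq, sq = sw$sp))
  }
  out <- list()
  # vectorized over Q segments for each P segment
  q0 <- Q$pts[-nrow(Q$pts), , drop = FALSE]
  q1 <- Q$pts[-1L, , drop = FALSE]
  for (i in seq_len(np)) {
    res <- segseg_distance(P$pts[i, ], P$pts[i + 1L, ], q0, q1)
    hit <- which(res$dist < thresh)
    if (length(hit) > 0L) {
      out[[length(out) + 1L]] <- tibble::tibble(
        i = i, j = hit, dist = res$dist[hit],
        sp = res$sp[hit], sq = res$sq[hit]
      )
    }
  }
  if (length(out) == 0L) return(NULL)
  dplyr::bind_rows(out)
}

# distance between segment (p0, p1) and many segments (q0, q1 rows);
# standard clamped closest-point computation, vectorized over rows
segseg_distance <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0                       # length-3
  d2 <- q1 - q0                       # n x 3
  r <- -sweep(q0, 2L, p0)             # p0 - q0, n x 3
  a <- sum(d1 * d1)
  e <- rowSums(d2 * d2)
  f <- rowSums(d2 * r)
  cvec <- drop(r %*% d1)
  b <- drop(d2 %*% d1)
  denom <- a * e - b^2
  s <- ifelse(denom > 1e-30, (b * f - cvec * e) / denom, 0)
  s <- pmin(pmax(s, 0), 1)
  t <- ifelse(e > 1e-30, (b * s + f) / e, 0)
  t <- pmin(pmax(t, 0), 1)
  # re-clamp s for clamped t
  s <- if (a > 1e-30) (b * t - cvec) / a else rep(0, length(t))
  s <- pmin(pmax(s, 0), 1)
  cp <- matrix(p0, nrow(q0), 3L, byrow = TRUE) + outer(s, d1)
  cq <- q0 + d2 * t
  list(dist = sqrt(rowSums((cp - cq)^2)), sp = s, sq = t, cp = cp, cq = cq)
}

# refine one candidate intersection: a few grid-shrink passes to land in
# the right basin, then Gauss-Newton on the parameter pair (distances are
# always direct point differences -- the expanded |P|^2+|Q|^2-2PQ form
# loses ~6 digits at these coordinate magnitudes)
refine_intersection <- function(c1, c2, t1, t2, w1, w2, iters = 4L, nfine = 33L) {
  s1 <- max(curve_knots(c1))
  s2 <- max(curve_knots(c2))
  for (it in seq_len(iters)) {
    g1 <- seq(max(0, t1 - w1), min(s1, t1 + w1), length.out = nfine)
    g2 <- seq(max(0, t2 - w2), min(s2, t2 + w2), length.out = nfine)
    P <- curve_eval(c1, g1)
    Q <- curve_eval(c2, g2)
    best_d <- Inf
    for (j in seq_len(nfine)) {
      dj <- (P[, 1] - Q[j, 1])^2 + (P[, 2] - Q[j, 2])^2 + (P[, 3] - Q[j, 3])^2
      i <- which.min(dj)
      if (dj[i] < best_d) {
        best_d <- dj[i]
        t1 <- g1[i]
        t2 <- g2[j]
      }
    }
    w1 <- w1 * 0.25
    w2 <- w2 * 0.25
  }
  h1 <- s1 * 1e-7 + 1e-9
  h2 <- s2 * 1e-7 + 1e-9
  for (it in 1:40) {
    p <- drop(curve_eval(c1, t1))
    q <- drop(curve_eval(c2, t2))
    r <- p - q
    dp <- drop(curve_eval(c1, min(t1 + h1, s1)) - curve_eval(c1, max(t1 - h1, 0))) /
      (min(t1 + h1, s1) - max(t1 - h1, 0))
    dq <- drop(curve_eval(c2, min(t2 + h2, s2)) - curve_eval(c2, max(t2 - h2, 0))) /
      (min(t2 + h2, s2) - max(t2 - h2, 0))
    g <- c(sum(dp * r), -sum(dq * r))
    a11 <- sum(dp * dp)
    a12 <- -sum(dp * dq)
    a22 <- sum(dq * dq)
    det <- a11 * a22 - a12^2
    if (!is.finite(det) || det < 1e-20) break
    step <- c(a22 * g[1] - a12 * g[2], a11 * g[2] - a12 * g[1]) / det
    t1n <- min(max(t1 - step[1], 0), s1)
    t2n <- min(max(t2 - step[2], 0), s2)
    if (abs(t1n - t1) + abs(t2n - t2) < 1e-12 * (s1 + s2)) {
      t1 <- t1n
      t2 <- t2n
      break
    }
    t1 <- t1n
    t2 <- t2n
  }
  list(t1 = t1, t2 = t2,
       point = (curve_eval(c1, t1) + curve_eval(c2, t2)) / 2,
       dist = sqrt(sum((curve_eval(c1, t1) - curve_eval(c2, t2))^2)))
}

#' Intersection profile of two feature curves
#'
#' Finds the intersection points of two spline curves (to tolerance `tol`,
#' mm) and classifies each as endpoint-endpoint, endpoint-interior or
#' interior-interior; "endpoint" means within `tol` of a curve terminus.
#' Tangential touches count once. Colinear overlap of positive length is an
#' error.
#'
#' @param c1,c2 `feature_curve` objects.
#' @param tol Geometric tolerance, mm.
#' @return Tibble with columns `x`, `y`, `z`, `t1`, `t2`, `class`
#'   (zero rows when disjoint).
#' @export
intersection_profile <- function(c1, c2, tol = 1e-6) {
  P <- curve_polyline(c1)
  Q <- curve_polyline(c2)
  span1 <- max(P$t)
  span2 <- max(Q$t)
  coarse_tol <- max(tol, 0.5)
  cand <- segment_candidates(P, Q, coarse_tol)
  if (is.null(cand)) {
    return(tibble::tibble(x = double(), y = double(), z = double(),
                          t1 = double(), t2 = double(), class = character()))
  }
  # overlap guard: a long contiguous run of touching segments means the
  # curves coincide over positive length
  touching <- cand[cand$dist < tol, , drop = FALSE]
  if (nrow(touching) > 0L) {
    runs <- sort(unique(touching$i))
    if (length(runs) > 4L && all(diff(runs) == 1L)) {
      stop("degenerate overlap: curves coincide over positive length", call. = FALSE)
    }
  }
  cand$t1 <- P$t[cand$i] + cand$sp * (P$t[cand$i + 1L] - P$t[cand$i])
  cand$t2 <- Q$t[cand$j] + cand$sq * (Q$t[cand$j + 1L] - Q$t[cand$j])
  # cluster candidates in parameter space
  cand <- cand[order(cand$t1), , drop = FALSE]
  gap <- max(span1, span2) * 0.02 + 1e-9
  cluster <- cumsum(c(1, diff(cand$t1) > gap | abs(diff(cand$t2)) > gap))
  hits <- list()
  for (cl in unique(cluster)) {
    sub <- cand[cluster == cl, , drop = FALSE]
    seed <- sub[which.min(sub$dist), ]
    w1 <- max(diff(range(sub$t1)), span1 / length(P$t)) + 1e-9
    w2 <- max(diff(range(sub$t2)), span2 / length(Q$t)) + 1e-9
    ref <- refine_intersection(c1, c2, seed$t1, seed$t2, w1 * 2, w2 * 2)
    if (ref$dist < tol) hits[[length(hits) + 1L]] <- ref
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(x = double(), y = double(), z = double(),
                          t1 = double(), t2 = double(), class = character()))
  }
  pt <- do.call(rbind, purrr::map(hits, "point"))
  t1 <- purrr::map_dbl(hits, "t1")
  t2 <- purrr::map_dbl(hits, "t2")
  # merge duplicate hits (tangential touches count once)
  keep <- rep(TRUE, length(t1))
  if (length(t1) > 1L) {
    for (i in seq_along(t1)[-1L]) {
      near <- which(keep[seq_len(i - 1L)])
      if (any(sqrt(rowSums((pt[near, , drop = FALSE] -
                              matrix(pt[i, ], length(near), 3L, byrow = TRUE))^2)) < 1e-3)) {
        keep[i] <- FALSE
      }
    }
  }
  pt <- pt[keep, , drop = FALSE]
  t1 <- t1[keep]
  t2 <- t2[keep]
  at_end <- function(curve, t, pos) {
    if (curve$closed) return(FALSE) # a closed curve has no terminus
    ends <- curve$points[c(1L, nrow(curve$points)), , drop = FALSE]
    min(sqrt(rowSums(sweep(ends, 2L, pos)^2))) < max(1e-6, 1e-3)
  }
  cls <- vapply(seq_along(t1), function(i) {
    e1 <- at_end(c1, t1[i], pt[i, ])
    e2 <- at_end(c2, t2[i], pt[i, ])
    if (e1 && e2) "endpoint-endpoint"
    else if (e1 || e2) "endpoint-interior"
    else "interior-interior"
  }, character(1))
  tibble::tibble(x = pt[, 1], y = pt[, 2], z = pt[, 3],
                 t1 = t1, t2 = t2, class = cls)
}

#' Topological relation label between two feature curves
#'
#' Boundary-internal (`BI`) relations are labeled by the number of
#' intersection points: none -> `BI_0`, one -> `BI_11`, two -> `BI_21`.
#' Internal-internal (`II`) relations are labeled by the position class of
#' the intersection: none -> `II_0`, endpoint-endpoint -> `II_11`,
#' endpoint-interior -> `II_12`, interior-interior -> `II_13`; with several
#' hits the highest class present wins.
#'
#' @inheritParams intersection_profile
#' @return Character label.
#' @export
classify_relation <- function(c1, c2, tol = 1e-6) {
  if (c1$kind == "boundary" && c2$kind == "boundary") {
    stop("the model has a single boundary curve; two boundary curves cannot be related",
         call. = FALSE)
  }
  hits <- intersection_profile(c1, c2, tol)
  n <- nrow(hits)
  if (c1$kind != c2$kind) {
    return(c("BI_0", "BI_11", "BI_21")[min(n, 2L) + 1L])
  }
  if (n == 0L) return("II_0")
  rank <- c("endpoint-endpoint" = 1L, "endpoint-interior" = 2L,
            "interior-interior" = 3L)
  paste0("II_1", max(rank[hits$class]))
}

#' Topology (adjacency) matrix of a curve skeleton
#'
#' Pairwise relation labels over all curves; the diagonal holds the curve
#' kinds (`B` / `I`). Exactly one boundary curve is required.
#'
#' @param curves List of `feature_curve` objects.
#' @param tol Geometric tolerance, mm.
#' @return Symmetric character matrix with curve ids as dimnames, class
#'   `topology_matrix`.
#' @export
topology_matrix <- function(curves, tol = 1e-6) {
  kinds <- purrr::map_chr(curves, "kind")
  if (sum(kinds == "boundary") != 1L) {
    stop("need exactly one boundary curve", call. = FALSE)
  }
  n <- length(curves)
  ids <- purrr::imap_chr(curves, function(cv, i) cv$id %||% paste0("C", i - 1L))
  m <- matrix("", n, n, dimnames = list(ids, ids))
  diag(m) <- ifelse(kinds == "boundary", "B", "I")
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      lab <- classify_relation(curves[[i]], curves[[j]], tol)
      m[i, j] <- lab
      m[j, i] <- lab
    }
  }
  structure(m, class = c("topology_matrix", "matrix"))
}

#' Compare a topology matrix with a template
#'
#' @param m,template `topology_matrix` objects of equal dimension.
#' @return Tibble of mismatched cells (`row`, `col`, `found`, `expected`);
#'   zero rows means structurally valid.
#' @export
validate_topology <- function(m, template) {
  if (!all(dim(m) == dim(template))) {
    stop("topology matrices have different dimensions", call. = FALSE)
  }
  idx <- which(unclass(m) != unclass(template) & upper.tri(m, diag = TRUE),
               arr.ind = TRUE)
  tibble::tibble(
    row = rownames(m)[idx[, 1L]],
    col = colnames(m)[idx[, 2L]],
    found = m[idx],
    expected = template[idx]
  )
}

#' The published adjacency matrix of the eagle-shaped plate skeleton
#'
#' Structural constraints of the twelve feature curves: the closed boundary
#' `C0`, tail/head ridge curves `C1`/`C2`, and costal curves `C3..C11`.
#'
#' @return A 12 x 12 `topology_matrix`.
#' @export
eagle_topology_reference <- function() {
  ids <- paste0("C", 0:11)
  m <- matrix("II_0", 12L, 12L, dimnames = list(ids, ids))
  diag(m) <- c("B", rep("I", 11L))
  set <- function(i, j, lab) {
    m[i + 1L, j + 1L] <<- lab
    m[j + 1L, i + 1L] <<- lab
  }
  set(0, 1, "BI_11"); set(0, 2, "BI_11")
  for (j in 3:11) set(0, j, "BI_21")
  set(1, 2, "II_11")
  set(1, 9, "II_12"); set(1, 10, "II_13"); set(1, 11, "II_13")
  for (j in 3:8) set(2, j, "II_13")
  set(2, 9, "II_12")
  structure(m, class = c("topology_matrix", "matrix"))
}
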