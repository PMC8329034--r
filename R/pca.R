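#' Eigensystem of a correlation matrix
#'
#' Eigendecomposition with descending eigenvalues, unit eigenvectors, a sign
#' convention (each eigenvector's largest-magnitude entry is positive), and
#' per-component variance contribution rates \eqn{r_k = \lambda_k / p}.
#'
#' `eigen_system()` can also be fed eigenvalues directly (e.g. published
#' contribution rates times p) when only retention arithmetic is needed.
#'
#' @param corr Symmetric correlation matrix.
#' @param values Numeric vector of eigenvalues (descending or not).
#' @param vectors Optional matrix of eigenvectors in columns.
#' @param p Number of variables the eigenvalues refer to (defaults to
#'   `length(values)`); the denominator of the contribution rates.
#' @return An `eigen_system`: list with `values`, `vectors`, `rates`,
#'   `cumulative`, `p`.
#' @export
pca_eigen <- function(corr) {
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  e <- eigen((corr + t(corr)) / 2, symmetric = TRUE)
  eigen_system(e$values, e$vectors, p = ncol(corr))
}

#' @rdname pca_eigen
#' @export
eigen_system <- function(values, vectors = NULL, p = length(values)) {
  if (length(values) == 0L) stop("empty eigensystem", call. = FALSE)
  ord <- order(values, decreasing = TRUE)
  values <- values[ord]
  if (!is.null(vectors)) {
    vectors <- as.matrix(vectors)[, ord, drop = FALSE]
    # sign convention: largest-magnitude entry of each column positive
    for (k in seq_len(ncol(vectors))) {
      i <- which.max(abs(vectors[, k]))
      if (vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
    }
  }
  structure(
    list(
      values = values,
      vectors = vectors,
      rates = values / p,
      cumulative = cumsum(values / p),
      p = p
    ),
    class = "eigen_system"
  )
}

#' @export
print.eigen_system <- function(x, ...) {
  cat(sprintf("<eigen_system: %d eigenvalues over p = %d variables>\n",
              length(x$values), x$p))
  print(tibble::tibble(
    component = seq_along(x$values),
    eigenvalue = x$values,
    rate = x$rates,
    cumulative = x$cumulative
  ), n = 10)
  invisible(x)
}

#' Component retention rule
#'
#' Retains the smallest number of leading components whose cumulative
#' variance contribution rate reaches `var_threshold`, subject to every
#' retained eigenvalue exceeding `eig_floor` (components with eigenvalues at
#' or below the floor are never retained; when the two criteria conflict the
#' eigenvalue floor wins and a warning is attached to the result).
#'
#' @param eig An `eigen_system`.
#' @param var_threshold Cumulative contribution rate to reach (default 0.90,
#'   inclusive).
#' @param eig_floor Strict lower bound on retained eigenvalues (default 0.5).
#' @return Integer `k`, with attribute `floor_limited` when the eigenvalue
#'   floor truncated the variance criterion.
#' @export
retain_components <- function(eig, var_threshold = 0.90, eig_floor = 0.5) {
  stopifnot(inherits(eig, "eigen_system"))
  hit <- which(eig$cumulative >= var_threshold - 1e-12)
  k_var <- if (length(hit) == 0L) length(eig$values) else hit[1L]
  k_floor <- sum(eig$values > eig_floor)
  if (k_floor == 0L) {
    stop("no eigenvalue exceeds the retention floor", call. = FALSE)
  }
  if (k_var > k_floor) {
    warning(
      sprintf(
        "variance criterion wants k = %d but only %d eigenvalue(s) exceed the floor %.3g; floor wins",
        k_var, k_floor, eig_floor
      ),
      call. = FALSE
    )
    return(structure(k_floor, floor_limited = TRUE))
  }
  structure(as.integer(k_var), floor_limited = FALSE)
}

#' Retained loadings of an eigensystem
#'
#' The first `k` eigenvectors as a raw [loading_matrix()] (components in
#' rows).
#'
#' @param eig An `eigen_system` carrying eigenvectors.
#' @param k Number of components.
#' @param variables Variable names.
#' @return A raw `loading_matrix` (k x p).
#' @export
retained_loadings <- function(eig, k, variables = NULL) {
  stopifnot(inherits(eig, "eigen_system"), !is.null(eig$vectors))
  loading_matrix(
    t(eig$vectors[, seq_len(k), drop = FALSE]),
    variables = variables %||% paste0("V", seq_len(nrow(eig$vectors))),
    rotated = FALSE
  )
}

#' Principal-component scores
#'
#' Scores are the plain matrix-vector product of the loading rows with the
#' standardized parameter vector: \eqn{s_i = \sum_j a_{ij} x_j}.
#'
#' @param x Standardized parameter vector (length p), or an n x p matrix /
#'   data frame of standardized subjects.
#' @param loadings A `loading_matrix` (k x p).
#' @return For a vector input, a named numeric vector of k scores; for a
#'   matrix/data frame, a tibble with one score column per component.
#' @export
component_scores <- function(x, loadings) {
  a <- unclass(loadings)
  if (is.data.frame(x)) x <- cohort_matrix(x, colnames(a))
  if (is.matrix(x)) {
    if (ncol(x) != ncol(a)) {
      stop(sprintf("x has %d columns but loadings expect %d", ncol(x), ncol(a)),
           call. = FALSE)
    }
    s <- x %*% t(a)
    colnames(s) <- rownames(a)
    return(tibble::as_tibble(s))
  }
  if (length(x) != ncol(a)) {
    stop(sprintf("x has length %d but loadings expect %d", length(x), ncol(a)),
         call. = FALSE)
  }
  drop(a %*% x)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax criterion (variance of squared
#' loadings), Kaiser-normalized. Communalities are preserved. A
#' single-component matrix is returned unchanged with a note attribute.
#'
#' @param loadings A raw `loading_matrix` with k >= 1 components.
#' @param normalize Kaiser row(variable)-normalization, default `TRUE`.
#' @param eps Convergence tolerance on the criterion.
#' @return A `loading_matrix` flagged as rotated, with attribute `rotation`
#'   (the k x k orthogonal matrix).
#' @export
rotate_loadings <- function(loadings, normalize = TRUE, eps = 1e-10) {
  a <- unclass(loadings)
  if (nrow(a) < 2L) {
    out <- loading_matrix(a, variables = colnames(a), rotated = TRUE)
    attr(out, "note") <- "single component: rotation is the identity"
    attr(out, "rotation") <- diag(1)
    return(out)
  }
  v <- stats::varimax(t(a), normalize = normalize, eps = eps)
  out <- loading_matrix(t(as.matrix(v$loadings)),
                        variables = colnames(a), rotated = TRUE)
  rownames(out) <- rownames(a)
  attr(out, "rotation") <- as.matrix(v$rotmat)
  out
}

#' Varimax criterion value of a loading matrix
#'
#' The raw (un-normalized) varimax criterion: sum over components of the
#' variance of the squared loadings. Used to verify rotation optimality.
#'
#' @param loadings Matrix or `loading_matrix`, components in rows.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  a2 <- unclass(loadings)^2
  p <- ncol(a2)
  sum(rowSums(a2^2) / p - (rowSums(a2) / p)^2)
}

#' Dominant parameters per rotated component
#'
#' Assigns every variable to the component carrying its largest absolute
#' rotated loading, and reports per-component parameter lists in schema
#' (column) order. Ties within `tol` go to the lower component index and are
#' flagged.
#'
#' @param rotated A rotated `loading_matrix`.
#' @param tol Tie tolerance.
#' @return Tibble with columns `parameter`, `component`, `loading`, `tied`.
#' @export
dominant_parameters <- function(rotated, tol = 1e-9) {
  a <- abs(unclass(rotated))
  comp <- integer(ncol(a))
  tied <- logical(ncol(a))
  for (j in seq_len(ncol(a))) {
    best <- max(a[, j])
    hits <- which(a[, j] >= best - tol)
    comp[j] <- hits[1L]
    tied[j] <- length(hits) > 1L
  }
  tibble::tibble(
    parameter = colnames(rotated),
    component = comp,
    loading = unclass(rotated)[cbind(comp, seq_len(ncol(a)))],
    tied = tied
  )
}

#' Variance-weighted composite score
#'
#' The final evaluation value of a subject: the weighted sum of its
#' component scores, the weight of each component being its variance
#' contribution rate. `normalized = TRUE` divides by the sum of the rates.
#'
#' @param scores Numeric vector of component scores, or a tibble/matrix of
#'   per-subject scores (components in columns).
#' @param rates Contribution rates, one per component.
#' @param normalized Divide by `sum(rates)` (default `FALSE`).
#' @return Scalar (vector input) or numeric vector, one value per subject.
#' @export
composite_score <- function(scores, rates, normalized = FALSE) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  w <- rates
  if (normalized) w <- w / sum(w)
  if (is.matrix(scores)) {
    if (ncol(scores) != length(w)) {
      stop("scores and rates dimensions differ", call. = FALSE)
    }
    return(drop(scores %*% w))
  }
  if (length(scores) != length(w)) {
    stop("scores and rates dimensions differ", call. = FALSE)
  }
  sum(scores * w)
}

#' Tertile classification of composite scores
#'
#' Splits subjects into three morphological classes by tertiles of the
#' composite score (lowest third is class 1). Ties are broken by subject
#' order.
#'
#' @param composites Numeric vector of composite scores (n >= 3).
#' @return Integer vector of class labels in \{1, 2, 3\}.
#' @export
classify_cohort <- function(composites) {
  n <- length(composites)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (max(composites) - min(composites) == 0) {
    stop("degenerate scores: all composite scores identical", call. = FALSE)
  }
  r <- rank(composites, ties.method = "first")
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  1L + (r > cut1) + (r > cut2)
}

#' Per-parameter one-way ANOVA across morphological classes
#'
#' Classical equal-variance one-way ANOVA of every parameter against the
#' class labels, mirroring per-parameter significance reporting (no
#' multiple-testing correction).
#'
#' @inheritParams standardize_cohort
#' @param labels Class labels, one per subject, >= 2 subjects per class.
#' @return Tibble with columns `parameter`, `statistic` (F), `p.value`;
#'   attribute `significant_fraction` gives the share of parameters with
#'   p < 0.05.
#' @export
anova_by_class <- function(data, labels, parameters = NULL) {
  m <- cohort_matrix(data, parameters)
  labels <- as.factor(labels)
  if (any(table(labels) < 2L)) {
    stop("every class needs at least 2 subjects", call. = FALSE)
  }
  res <- purrr::map(seq_len(ncol(m)), function(j) {
    fit <- stats::aov(m[, j] ~ labels)
    s <- summary(fit)[[1L]]
    c(statistic = s[["F value"]][1L], p.value = s[["Pr(>F)"]][1L])
  })
  out <- tibble::tibble(
    parameter = colnames(m),
    statistic = purrr::map_dbl(res, "statistic"),
    p.value = purrr::map_dbl(res, "p.value")
  )
  attr(out, "significant_fraction") <- mean(out$p.value < 0.05)
  out
}

#' Reconstruct standardized parameters from component scores
#'
#' The least-squares reconstruction \eqn{\hat x = A^\top s}: the orthogonal
#' projection of the subject onto the span of the retained components. Only
#' valid for raw loadings (orthonormal rows); rotated loadings are refused.
#'
#' @param scores Numeric vector of k component scores.
#' @param loadings Raw `loading_matrix` (k x p).
#' @return Standardized parameter vector of length p (named).
#' @export
reconstruct_parameters <- function(scores, loadings) {
  if (is_rotated(loadings)) {
    stop("reconstruction requires raw (unrotated) loadings", call. = FALSE)
  }
  a <- unclass(loadings)
  if (length(scores) != nrow(a)) {
    stop("scores length does not match number of components", call. = FALSE)
  }
  drop(crossprod(a, scores))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
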