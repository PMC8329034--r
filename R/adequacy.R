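#' Pearson correlation matrix of a (standardized) cohort
#'
#' @inheritParams standardize_cohort
#' @return A p x p correlation matrix with attribute `n` (subjects used) and
#'   attribute `rank_deficient` set when n <= p.
#' @export
cohort_correlation <- function(data, parameters = NULL) {
  m <- cohort_matrix(data, parameters)
  n <- nrow(m)
  r <- stats::cor(m)
  attr(r, "n") <- n
  if (n <= ncol(m)) {
    attr(r, "rank_deficient") <- TRUE
    warning(
      sprintf("n (%d) <= p (%d): correlation matrix is rank deficient", n, ncol(m)),
      call. = FALSE
    )
  }
  r
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO compares the summed squared simple correlations with the summed
#' squared partial correlations obtained from the inverse correlation
#' matrix:
#' \deqn{KMO = \sum_{i \ne j} r_{ij}^2 / (\sum_{i \ne j} r_{ij}^2 +
#'   \sum_{i \ne j} q_{ij}^2)}
#' with \eqn{q_{ij} = -S_{ij} / \sqrt{S_{ii} S_{jj}}}, \eqn{S = R^{-1}}.
#' Values near 1 mean the variables share enough correlation for PCA.
#'
#' @param corr Correlation matrix.
#' @return KMO statistic in \[0, 1\].
#' @export
kmo <- function(corr) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  off <- upper.tri(corr)
  r2 <- sum(corr[off]^2)
  if (r2 < .Machine$double.eps) {
    stop("no correlations to assess (correlation matrix is the identity)", call. = FALSE)
  }
  inv <- tryCatch(solve(corr), error = function(e) NULL)
  if (is.null(inv)) {
    warning("correlation matrix is singular; using pseudo-inverse", call. = FALSE)
    e <- eigen(corr, symmetric = TRUE)
    keep <- e$values > max(e$values) * 1e-12
    inv <- e$vectors[, keep, drop = FALSE] %*%
      (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  }
  d <- sqrt(diag(inv))
  q <- -inv / tcrossprod(d)
  q2 <- sum(q[off]^2)
  r2 / (r2 + q2)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity (no shared
#' correlation, PCA pointless):
#' \deqn{\chi^2 = -(n - 1 - (2p + 5)/6)\,\ln\det R,\qquad
#'   df = p(p-1)/2.}
#'
#' @param corr Correlation matrix.
#' @param n Number of subjects it was computed from.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
bartlett_sphericity <- function(corr, n) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  if (n <= p) stop("Bartlett's test needs n > p", call. = FALSE)
  det_r <- det(corr)
  if (!is.finite(det_r) || det_r <= 0) {
    stop("correlation matrix is singular (det <= 0)", call. = FALSE)
  }
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(det_r)
  df <- p * (p - 1) / 2
  list(
    statistic = stat,
    df = df,
    p.value = stats::pchisq(stat, df = df, lower.tail = FALSE)
  )
}
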