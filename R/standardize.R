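#' Standardize a cohort table
#'
#' Centers every parameter column to mean zero and scales it to unit sample
#' standard deviation (n - 1 denominator). The column means and SDs are kept
#' as attributes so the transform can be inverted exactly.
#'
#' @param data Cohort tibble: one subject per row, parameter columns named
#'   as in [femur_parameter_schema()] (non-parameter columns such as
#'   `subject` pass through untouched).
#' @param parameters Optional character vector restricting which columns are
#'   standardized; defaults to every schema column present.
#' @return A tibble of the same shape with attributes `center` and `scale`.
#' @seealso [unstandardize_cohort()]
#' @export
standardize_cohort <- function(data, parameters = NULL) {
  m <- cohort_matrix(data, parameters)
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  if (any(scale == 0)) {
    bad <- colnames(m)[scale == 0]
    stop(
      "cannot standardize constant parameter(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  z <- sweep(sweep(m, 2L, center), 2L, scale, "/")
  out <- data
  out[, colnames(m)] <- tibble::as_tibble(z)
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Invert [standardize_cohort()]
#'
#' @param data A tibble produced by [standardize_cohort()] (or any tibble of
#'   z-scores) carrying `center`/`scale` attributes, or with them supplied
#'   explicitly.
#' @param center,scale Named numeric vectors overriding the attributes.
#' @return Tibble on the original measurement scale.
#' @export
unstandardize_cohort <- function(data, center = attr(data, "center"),
                                 scale = attr(data, "scale")) {
  if (is.null(center) || is.null(scale)) {
    stop("no center/scale information available", call. = FALSE)
  }
  cols <- names(center)
  m <- cohort_matrix(data, cols)
  x <- sweep(sweep(m, 2L, scale[cols], "*"), 2L, center[cols], "+")
  out <- data
  out[, cols] <- tibble::as_tibble(x)
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}

#' Per-parameter summary statistics
#'
#' Sample mean, standard deviation (n - 1) and adjusted Fisher-Pearson
#' skewness for every parameter column.
#'
#' @inheritParams standardize_cohort
#' @return Tibble with columns `name`, `mean`, `sd`, `skewness`.
#' @export
cohort_summary <- function(data, parameters = NULL) {
  m <- cohort_matrix(data, parameters)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 subjects (skewness undefined)", call. = FALSE)
  tibble::tibble(
    name = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2L, stats::sd),
    skewness = apply(m, 2L, skewness_adjusted)
  )
}

# Adjusted Fisher-Pearson skewness: g1 * sqrt(n(n-1)) / (n-2).
skewness_adjusted <- function(x) {
  n <- length(x)
  if (n < 3L) stop("skewness needs n >= 3", call. = FALSE)
  d <- x - mean(x)
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  if (m2 == 0) return(0)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
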