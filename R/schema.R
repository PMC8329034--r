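#' Femoral parameter schema
#'
#' The 28 named femoral morphological parameters used throughout the package
#' (9 proximal, 3 shaft, 16 distal), plus the overall femur length `H_f` as a
#' standalone entry. Proximal parameters are the vector `X1..X9`, distal
#' parameters the vector `Y1..Y16`; the ordering here is the canonical column
#' order for cohort tables.
#'
#' @return A tibble with columns `name`, `region`
#'   (`proximal`/`shaft`/`distal`/`overall`) and `unit` (`mm`, `degree` or
#'   `ratio`).
#' @export
#' @examples
#' femur_parameter_schema()
femur_parameter_schema <- function() {
  tibble::tibble(
    name = c(
      # proximal X1..X9
      "H_fh", "A_fn", "L_fhs", "L_fn", "D_fh", "D_fn", "L_t", "H_t1", "H_t2",
      # shaft
      "D_fs", "H_fs", "A_fs",
      # distal Y1..Y16
      "L_df", "L_m", "L_l", "L_a", "L_p", "H_m", "H_l", "A_m",
      "A_l", "A_a", "A_p", "A_s", "H_tg", "H_ml", "C_f", "A_ml",
      # overall femur length
      "H_f"
    ),
    region = c(
      rep("proximal", 9L), rep("shaft", 3L), rep("distal", 16L), "overall"
    ),
    unit = c(
      "mm", "degree", "mm", "mm", "mm", "mm", "mm", "mm", "mm",
      "mm", "mm", "degree",
      "mm", "mm", "mm", "mm", "mm", "mm", "mm", "degree",
      "degree", "degree", "degree", "degree", "mm", "mm", "ratio", "degree",
      "mm"
    )
  )
}

#' Names of the parameters belonging to one femoral region
#'
#' @param region One of `"proximal"`, `"shaft"`, `"distal"`, `"overall"`.
#' @return Character vector of parameter names in schema order.
#' @export
region_parameters <- function(region = c("proximal", "shaft", "distal", "overall")) {
  region <- match.arg(region)
  sch <- femur_parameter_schema()
  sch$name[sch$region == region]
}

#' Reference cohort distribution parameters
#'
#' Per-parameter mean and standard deviation of the reference cohort of 100
#' adult right femurs (lengths in mm, angles in degrees). These are the
#' default distribution parameters of [generate_cohort()].
#'
#' @return A tibble with columns `name`, `mean`, `sd`.
#' @export
femur_reference_stats <- function() {
  tibble::tibble(
    name = femur_parameter_schema()$name,
    mean = c(
      47.95, 126.18, 38.75, 50.80, 43.33, 33.08, 65.86, 10.73, 17.57,
      25.94, 269.19, 173.39,
      75.10, 56.03, 59.95, 32.77, 52.06, 55.35, 59.73, 81.33,
      85.60, 8.25, 4.13, 134.11, 6.04, 4.37, 1.25, 12.98,
      420.072
    ),
    sd = c(
      5.33, 6.12, 6.25, 6.19, 3.40, 3.25, 4.03, 1.09, 2.36,
      2.23, 16.64, 1.51,
      6.00, 3.74, 4.00, 2.53, 4.05, 3.71, 3.98, 1.87,
      1.97, 2.85, 1.63, 4.19, 0.75, 0.51, 0.09, 2.86,
      22.968
    )
  )
}

#' The reference mean femur as a named parameter vector
#'
#' @return Named numeric vector over all 29 schema entries, each at its
#'   reference cohort mean.
#' @export
mean_femur_parameters <- function() {
  stats <- femur_reference_stats()
  stats::setNames(stats$mean, stats$name)
}

# Internal: check a data frame holds the schema parameter columns for a region
# (or all of them). Returns the parameter column names in schema order.
assert_cohort_columns <- function(data, parameters = NULL) {
  if (is.null(parameters)) {
    parameters <- setdiff(femur_parameter_schema()$name, character())
    parameters <- intersect(parameters, names(data))
    if (length(parameters) == 0L) {
      stop("no femoral parameter columns found in `data`", call. = FALSE)
    }
  } else {
    missing <- setdiff(parameters, names(data))
    if (length(missing) > 0L) {
      stop(
        "cohort is missing parameter columns: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
  }
  parameters
}

# Internal: numeric matrix of the parameter columns of a cohort tibble.
cohort_matrix <- function(data, parameters = NULL) {
  parameters <- assert_cohort_columns(data, parameters)
  m <- as.matrix(as.data.frame(data)[, parameters, drop = FALSE])
  if (!is.numeric(m)) stop("parameter columns must be numeric", call. = FALSE)
  if (anyNA(m)) stop("cohort contains missing values", call. = FALSE)
  m
}
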