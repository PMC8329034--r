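#' Loading matrix constructor
#'
#' A loading matrix stores one retained principal component per row and one
#' original variable per column (element `[i, j]` is the weight of variable
#' `j` in component `i`). Raw (unrotated) loadings are the unit-norm
#' eigenvectors of the correlation matrix; rotated loadings come out of
#' [rotate_loadings()].
#'
#' @param values Numeric matrix, components in rows, variables in columns.
#' @param variables Character vector of variable names (defaults to the
#'   matrix column names).
#' @param rotated Logical flag; raw eigenvector loadings are `FALSE`.
#' @return A `loading_matrix` object (a matrix with attributes).
#' @export
loading_matrix <- function(values, variables = colnames(values), rotated = FALSE) {
  values <- as.matrix(values)
  if (is.null(variables)) {
    variables <- paste0("V", seq_len(ncol(values)))
  }
  stopifnot(length(variables) == ncol(values))
  colnames(values) <- variables
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("PC", seq_len(nrow(values)))
  }
  structure(values, class = c("loading_matrix", "matrix"), rotated = isTRUE(rotated))
}

#' @export
print.loading_matrix <- function(x, ...) {
  cat(sprintf(
    "<loading_matrix: %d components x %d variables, %s>\n",
    nrow(x), ncol(x), if (is_rotated(x)) "rotated" else "raw"
  ))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Is a loading matrix rotated?
#' @param x A `loading_matrix`.
#' @return Logical.
#' @export
is_rotated <- function(x) isTRUE(attr(x, "rotated"))

#' Per-variable communalities of a loading matrix
#'
#' The communality of a variable is its sum of squared loadings over the
#' retained components; orthogonal rotation leaves it unchanged.
#'
#' @param x A `loading_matrix`.
#' @return Named numeric vector, one entry per variable.
#' @export
communalities <- function(x) {
  colSums(unclass(x)^2)
}

#' Proximal femur loading matrix (printed reference)
#'
#' The published 4-component loading matrix of the nine proximal femoral
#' parameters. Each row is the unit-norm eigenvector of one retained
#' component; columns follow the proximal schema order `X1..X9`
#' (`H_fh` ... `H_t2`).
#'
#' @return A raw `loading_matrix` (4 x 9).
#' @export
proximal_loadings <- function() {
  # columns of the printed table (one eigenvector each), transposed so that
  # components sit in rows
  a <- rbind(
    c(0.348, -0.070, 0.223, 0.243, 0.466, 0.446, 0.450, 0.275, 0.269),
    c(0.291, 0.448, -0.571, -0.441, 0.058, 0.137, 0.108, 0.326, -0.233),
    c(0.384, 0.606, -0.058, 0.353, -0.010, -0.140, -0.177, -0.421, 0.359),
    c(0.289, 0.137, 0.283, 0.457, -0.178, -0.156, -0.004, 0.273, -0.691)
  )
  loading_matrix(a, variables = region_parameters("proximal"), rotated = FALSE)
}

#' Distal femur loading matrix (printed reference)
#'
#' The published 7-component loading matrix of the sixteen distal femoral
#' parameters, kept verbatim as printed. Note that the printed seventh
#' column is internally inconsistent (it contains the value 1.588, which is
#' impossible for a loading); this fixture is therefore suitable for
#' input/output round trips and retention arithmetic, but not as numerical
#' ground truth. Use `normalize = TRUE` to renormalize every component row
#' to unit norm before using the matrix in reconstruction or mapping.
#'
#' @param normalize Renormalize rows to unit norm (default `FALSE`:
#'   verbatim as printed).
#' @return A raw `loading_matrix` (7 x 16).
#' @export
distal_loadings <- function(normalize = FALSE) {
  by_row <- rbind( # one printed table row (variable) per line, 7 components
    c(-0.020, -0.065, -0.069, -0.164, 0.157, 0.951, 0.944),
    c(0.425, -0.033, -0.185, 0.092, -0.094, 0.022, 0.866),
    c(0.425, -0.033, -0.185, 0.092, -0.094, 0.021, 0.866),
    c(0.230, -0.244, 0.227, -0.230, 0.431, -0.140, 0.988),
    c(0.268, -0.032, 0.357, -0.207, 0.384, -0.101, 0.984),
    c(0.420, -0.068, -0.198, 0.086, -0.095, 0.018, 0.867),
    c(0.427, -0.013, -0.174, 0.096, -0.094, 0.022, 0.862),
    c(-0.059, -0.486, -0.212, -0.101, -0.043, -0.053, 0.861),
    c(0.040, 0.489, 0.207, 0.080, 0.020, 0.016, 0.794),
    c(-0.042, -0.138, 0.171, 0.581, 0.279, 0.053, 0.668),
    c(-0.007, -0.142, 0.064, 0.607, 0.309, 0.105, 0.819),
    c(0.001, 0.106, -0.472, -0.159, 0.606, -0.166, 0.747),
    c(0.162, -0.254, 0.535, -0.041, -0.192, 0.019, 0.979),
    c(0.278, 0.393, 0.082, 0.124, -0.037, 0.043, 0.812),
    c(-0.202, 0.115, -0.182, 0.251, -0.011, -0.106, 1.588),
    c(0.062, 0.415, 0.090, -0.128, 0.163, 0.079, 0.905)
  )
  b <- t(by_row)
  if (normalize) {
    b <- b / sqrt(rowSums(b^2))
  }
  loading_matrix(b, variables = region_parameters("distal"), rotated = FALSE)
}

#' Variance contribution rates of the retained components
#'
#' The published per-component variance contribution rates (eigenvalue over
#' the number of standardized variables), as fractions.
#'
#' @return Numeric vector: 4 proximal rates (summing to 0.90474) or 7 distal
#'   rates (summing to 0.93241).
#' @export
proximal_rates <- function() c(43.054, 25.449, 14.176, 7.795) / 100

#' @rdname proximal_rates
#' @export
distal_rates <- function() c(31.338, 22.293, 11.936, 9.589, 7.630, 6.112, 4.343) / 100

#' Read / write a loading matrix as CSV
#'
#' The CSV layout mirrors the published tables: variables in rows,
#' components in columns; the first column holds the variable names.
#'
#' @param x A `loading_matrix`.
#' @param path File path.
#' @param rotated Flag recorded on the matrix read back.
#' @return `write_loadings_csv()` returns `path` invisibly;
#'   `read_loadings_csv()` returns a `loading_matrix`.
#' @export
write_loadings_csv <- function(x, path) {
  df <- data.frame(variable = colnames(x), t(unclass(x)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_loadings_csv
#' @export
read_loadings_csv <- function(path, rotated = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  vars <- as.character(df[[1L]])
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  loading_matrix(m, variables = vars, rotated = rotated)
}
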