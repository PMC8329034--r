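#' Read / write cohort tables as CSV
#'
#' The cohort dialect: a header row of schema parameter names (`H_fh`,
#' `A_fn`, ..., `A_ml`, `H_f`), one subject per row, mm/degree units, UTF-8
#' with `.` decimal. A `subject` id column is added on read when absent.
#'
#' @param data Cohort tibble.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a tibble.
#' @export
write_cohort_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  schema <- femur_parameter_schema()$name
  found <- intersect(schema, names(df))
  if (length(found) == 0L) {
    stop("no schema parameter columns in ", path, call. = FALSE)
  }
  if (!"subject" %in% names(df)) {
    df <- dplyr::bind_cols(tibble::tibble(subject = seq_len(nrow(df))), df)
  }
  df
}

#' The shipped eagle-plate skeleton template
#'
#' The canonical twelve-curve skeleton, constructed by laying the published
#' Plate A parameters flat on a plane with parametric bump heights. Its
#' computed topology matrix equals the published adjacency matrix.
#'
#' @return A `skeleton_curves` object.
#' @export
eagle_template <- function() {
  grid <- build_feature_points(plate_preset("A"), plane_surface(length = 300),
                               heights = "parametric")
  build_skeleton(grid)
}

#' Write / read a skeleton template as JSON
#'
#' The template file stores curve ids, kinds, control points and the
#' expected topology matrix.
#'
#' @param skel A `skeleton_curves` object.
#' @param path File path.
#' @param template Expected `topology_matrix` stored alongside the curves
#'   (default: the published eagle-plate matrix).
#' @return `write_template_json()` returns `path` invisibly;
#'   `read_template_json()` returns a list of `feature_curve`s with the
#'   expected matrix as attribute `expected_topology`.
#' @export
write_template_json <- function(skel, path, template = eagle_topology_reference()) {
  curves <- lapply(skel, function(cv) {
    list(id = cv$id, kind = cv$kind, closed = cv$closed,
         points = unname(apply(cv$points, 1L, as.numeric, simplify = FALSE)))
  })
  jsonlite::write_json(
    list(units = "mm", curves = unname(curves),
         expected_topology = apply(unclass(template), 1L, as.list)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_template_json
#' @export
read_template_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  curves <- lapply(x$curves, function(cv) {
    pts <- do.call(rbind, lapply(cv$points, unlist))
    feature_curve(pts, kind = cv$kind, id = cv$id)
  })
  names(curves) <- vapply(curves, function(cv) cv$id, character(1))
  if (!is.null(x$expected_topology)) {
    ids <- names(curves)
    m <- do.call(rbind, lapply(x$expected_topology, unlist))
    dimnames(m) <- list(ids, ids)
    attr(curves, "expected_topology") <-
      structure(m, class = c("topology_matrix", "matrix"))
  }
  curves
}

#' Emit the published reference fixtures
#'
#' Writes every printed reference object to `dir`: the eagle template JSON
#' with the published adjacency matrix, the proximal/distal loading
#' matrices and contribution rates as CSV, the cohort distribution
#' parameters as CSV, and the three plate presets as JSON. Re-running
#' produces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_reference_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- function(...) file.path(dir, ...)
  write_loadings_csv(proximal_loadings(), p("proximal_loadings.csv"))
  write_loadings_csv(distal_loadings(), p("distal_loadings.csv"))
  utils::write.csv(
    data.frame(component = seq_along(proximal_rates()), rate = proximal_rates()),
    p("proximal_rates.csv"), row.names = FALSE
  )
  utils::write.csv(
    data.frame(component = seq_along(distal_rates()), rate = distal_rates()),
    p("distal_rates.csv"), row.names = FALSE
  )
  utils::write.csv(as.data.frame(femur_reference_stats()),
                   p("reference_stats.csv"), row.names = FALSE)
  for (w in c("A", "B", "C")) {
    write_semantic_json(plate_preset(w), p(sprintf("plate_%s.json", w)))
  }
  write_template_json(eagle_template(), p("eagle_template.json"))
  utils::write.csv(as.data.frame(unclass(eagle_topology_reference())),
                   p("eagle_topology.csv"), row.names = TRUE)
  invisible(list.files(dir, full.names = TRUE))
}
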