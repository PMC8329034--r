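#' Full principal-component feature extraction for one femoral region
#'
#' Runs the whole morphometric pipeline on a cohort table: standardization,
#' sampling-adequacy tests (KMO, Bartlett sphericity), eigendecomposition of
#' the correlation matrix, component retention, varimax rotation,
#' per-subject component scores, variance-weighted composite scores,
#' tertile classification and per-parameter ANOVA across the classes.
#'
#' @param data Cohort tibble, one subject per row.
#' @param region `"proximal"` or `"distal"` (the shaft block is deliberately
#'   never reduced: its parameters are few and weakly correlated and pass
#'   through unreduced).
#' @param var_threshold,eig_floor Retention rule, see [retain_components()].
#' @return A `femur_pca` object: list with `region`, `n`, `kmo`, `bartlett`,
#'   `eigen`, `k`, `loadings` (raw), `rotated`, `dominant`, `scores`
#'   (tibble), `composite`, `classes`, `anova`, `center`, `scale`.
#' @export
femur_pca <- function(data, region = c("proximal", "distal"),
                      var_threshold = 0.90, eig_floor = 0.5) {
  region <- match.arg(region)
  params <- region_parameters(region)
  std <- standardize_cohort(data, params)
  corr <- cohort_correlation(std, params)
  n <- attr(corr, "n")
  adequacy_kmo <- kmo(corr)
  bart <- bartlett_sphericity(corr, n)
  eig <- pca_eigen(corr)
  k <- retain_components(eig, var_threshold, eig_floor)
  loadings <- retained_loadings(eig, k, variables = params)
  rotated <- rotate_loadings(loadings)
  scores <- component_scores(std, loadings)
  names(scores) <- paste0(if (region == "proximal") "p" else "q", seq_len(k))
  comp <- composite_score(scores, eig$rates[seq_len(k)])
  classes <- classify_cohort(comp)
  anova <- anova_by_class(data, classes, params)
  structure(
    list(
      region = region, n = n,
      kmo = adequacy_kmo, bartlett = bart,
      eigen = eig, k = as.integer(k),
      loadings = loadings, rotated = rotated,
      dominant = dominant_parameters(rotated),
      scores = scores, composite = comp, classes = classes,
      anova = anova,
      center = attr(std, "center"), scale = attr(std, "scale")
    ),
    class = "femur_pca"
  )
}

#' @export
print.femur_pca <- function(x, ...) {
  cat(sprintf(
    "<femur_pca: %s region, n = %d, k = %d components (%.1f%% cumulative)>\n",
    x$region, x$n, x$k, 100 * x$eigen$cumulative[x$k]
  ))
  cat(sprintf("  KMO = %.3f, Bartlett p = %.3g\n", x$kmo, x$bartlett$p.value))
  invisible(x)
}

#' Tidy a femur PCA fit
#'
#' @param x A `femur_pca` object.
#' @param matrix Which loadings to return, `"rotated"` (default) or `"raw"`.
#' @param ... Unused.
#' @return A long tibble with `component`, `parameter`, `loading`.
#' @export
tidy.femur_pca <- function(x, matrix = c("rotated", "raw"), ...) {
  matrix <- match.arg(matrix)
  m <- unclass(if (matrix == "rotated") x$rotated else x$loadings)
  tibble::tibble(
    component = rep(seq_len(nrow(m)), times = ncol(m)),
    parameter = rep(colnames(m), each = nrow(m)),
    loading = as.vector(m)
  )
}

#' One-row summary of a femur PCA fit
#'
#' @param x A `femur_pca` object.
#' @param ... Unused.
#' @return One-row tibble: `region`, `n`, `kmo`, `bartlett_p`, `k`,
#'   `cumulative_rate`, `anova_significant_fraction`.
#' @export
glance.femur_pca <- function(x, ...) {
  tibble::tibble(
    region = x$region,
    n = x$n,
    kmo = x$kmo,
    bartlett_p = x$bartlett$p.value,
    k = x$k,
    cumulative_rate = x$eigen$cumulative[x$k],
    anova_significant_fraction = attr(x$anova, "significant_fraction")
  )
}

#' Scree / contribution-rate plot of a femur PCA fit
#'
#' @param object A `femur_pca` object.
#' @param ... Unused.
#' @return A ggplot: eigenvalues per component with the cumulative
#'   contribution rate overlaid.
#' @export
autoplot.femur_pca <- function(object, ...) {
  df <- tibble::tibble(
    component = seq_along(object$eigen$values),
    eigenvalue = object$eigen$values,
    cumulative = object$eigen$cumulative
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$eigenvalue), fill = "grey70") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$cumulative * max(.data$eigenvalue)),
      colour = "firebrick"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$cumulative * max(.data$eigenvalue)),
      colour = "firebrick"
    ) +
    ggplot2::geom_vline(xintercept = object$k + 0.5, linetype = 2) +
    ggplot2::labs(
      x = "component", y = "eigenvalue",
      title = sprintf("%s femur: %d components retained", object$region, object$k),
      subtitle = "red line: cumulative contribution rate (rescaled)"
    )
}

#' PCA report as a plain list (JSON-ready)
#'
#' @param fit A `femur_pca` object.
#' @return Nested list mirroring the report fields written by the CLI.
#' @export
pca_report <- function(fit) {
  list(
    region = fit$region,
    n = fit$n,
    kmo = fit$kmo,
    bartlett = fit$bartlett,
    eigenvalues = fit$eigen$values,
    rates = fit$eigen$rates,
    cumulative = fit$eigen$cumulative,
    k = fit$k,
    rotated_loadings = apply(unclass(fit$rotated), 1L, identity, simplify = FALSE),
    dominant = split(fit$dominant$parameter, fit$dominant$component),
    composite = fit$composite,
    classes = fit$classes,
    anova = list(
      parameter = fit$anova$parameter,
      statistic = fit$anova$statistic,
      p.value = fit$anova$p.value,
      significant_fraction = attr(fit$anova, "significant_fraction")
    )
  )
}
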