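#' Reconstruct a correlation matrix from retained loadings
#'
#' Builds the correlation implied by published loadings and variance
#' contribution rates: the retained part
#' \eqn{R_0 = \sum_k (r_k p)\, v_k v_k^\top} plus the residual variance
#' \eqn{p - \sum_k r_k p} spread isotropically over the orthogonal
#' complement of the retained components (uncorrelated residual noise), so
#' that the top-k eigenvalues of the reconstruction equal the printed
#' eigenvalues exactly before the diagonal is re-unitized. Eigenvalues are
#' then clipped to be nonnegative, the matrix re-symmetrized and its
#' diagonal re-unitized; the Frobenius norm of the total repair
#' (clipping + unitization) is reported.
#'
#' @param loadings Raw `loading_matrix` with unit-norm component rows.
#' @param rates Variance contribution rates in (0, 1), one per component.
#' @return Correlation matrix with attributes `repair_delta` (Frobenius
#'   norm of the repair applied after the raw construction) and
#'   `provenance`.
#' @export
reconstruct_correlation <- function(loadings, rates) {
  a <- unclass(loadings)
  k <- nrow(a)
  p <- ncol(a)
  stopifnot(length(rates) == k, all(rates > 0), all(rates < 1))
  row_norms <- sqrt(rowSums(a^2))
  if (any(abs(row_norms - 1) > 0.05)) {
    stop("loadings rows must be (approximately) unit norm; renormalize first",
         call. = FALSE)
  }
  lambda <- rates * p
  if (sum(lambda) > p * 1.05) {
    stop("inconsistent inputs: implied eigenvalues sum to more than p", call. = FALSE)
  }
  v <- a / row_norms
  r0 <- crossprod(v * sqrt(lambda)) # sum_k lambda_k v_k v_k^T
  c_res <- if (p > k) max(p - sum(lambda), 0) / (p - k) else 0
  r0 <- r0 + c_res * (diag(p) - crossprod(v))
  e <- eigen((r0 + t(r0)) / 2, symmetric = TRUE)
  clipped <- pmax(e$values, 1e-8)
  r1 <- e$vectors %*% (t(e$vectors) * clipped)
  r1 <- (r1 + t(r1)) / 2
  d <- sqrt(diag(r1))
  r1 <- r1 / tcrossprod(d)
  diag(r1) <- 1
  dimnames(r1) <- list(colnames(a), colnames(a))
  attr(r1, "repair_delta") <- sqrt(sum((r1 - r0)^2))
  attr(r1, "provenance") <- list(components = k, rates = rates)
  r1
}

#' Cohort simulation specification
#'
#' Defaults emulate the reference cohort: the per-parameter means/SDs of
#' [femur_reference_stats()] and the correlation structure reconstructed
#' from the published proximal and distal loading matrices (block-diagonal;
#' no cross-block information is published, so cross-block correlations are
#' zero and the 3 shaft parameters are uncorrelated). Overall femur length
#' `H_f` is drawn with its published moments, correlated 0.8 with shaft
#' length.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @param stats Tibble of `name`, `mean`, `sd` (defaults to the reference).
#' @param correlation `"reconstructed"` (default), `"identity"`, or a
#'   user-supplied 28 x 28 correlation matrix over the core parameters.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n, seed = 1L, stats = femur_reference_stats(),
                        correlation = "reconstructed") {
  stopifnot(n >= 1, all(stats$sd > 0))
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 stats = stats, correlation = correlation),
            class = "cohort_spec")
}

# Internal: assemble the 28 x 28 block-diagonal core correlation matrix.
core_correlation <- function(kind = "reconstructed") {
  params <- femur_parameter_schema()
  core <- params$name[params$region != "overall"]
  if (is.matrix(kind)) {
    stopifnot(nrow(kind) == length(core), ncol(kind) == length(core))
    ev <- eigen((kind + t(kind)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("user correlation matrix is not PSD; see reconstruct_correlation()",
           call. = FALSE)
    }
    r <- kind
    dimnames(r) <- list(core, core)
    return(r)
  }
  r <- diag(length(core))
  dimnames(r) <- list(core, core)
  if (identical(kind, "identity")) return(r)
  if (!identical(kind, "reconstructed")) {
    stop("correlation must be 'reconstructed', 'identity', or a matrix", call. = FALSE)
  }
  rp <- reconstruct_correlation(proximal_loadings(), proximal_rates())
  rd <- reconstruct_correlation(distal_loadings(normalize = TRUE), distal_rates())
  r[rownames(rp), colnames(rp)] <- rp
  r[rownames(rd), colnames(rd)] <- rd
  r
}

#' Generate a synthetic femoral cohort
#'
#' Draws multivariate normal standardized scores with the spec correlation
#' (Cholesky factor of the repaired matrix) and de-standardizes them with
#' the per-parameter means and SDs. The synthetic cohort is exactly normal:
#' the slight left skew of the real reference data (skewness -0.07 in femur
#' length) is deliberately not injected.
#'
#' @param spec A [cohort_spec()], or `n` when called as
#'   `generate_cohort(n, seed = ...)`.
#' @param seed Used only when `spec` is given as a plain count.
#' @return Tibble: `subject` id plus the 28 core parameters and `H_f`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  if (!inherits(spec, "cohort_spec")) spec <- cohort_spec(spec, seed = seed)
  stats <- spec$stats
  r <- core_correlation(spec$correlation)
  core <- rownames(r)
  ch <- chol(r + diag(1e-10, nrow(r)))
  n <- spec$n
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(n * length(core)), n, length(core)) %*% ch
  colnames(z) <- core
  # overall femur length: printed moments, correlated with shaft length
  rho <- if (identical(spec$correlation, "identity")) 0 else 0.8
  z_hf <- rho * z[, "H_fs"] + sqrt(1 - rho^2) * stats::rnorm(n)
  z <- cbind(z, H_f = z_hf)
  mu <- stats::setNames(stats$mean, stats$name)[colnames(z)]
  sd <- stats::setNames(stats$sd, stats$name)[colnames(z)]
  x <- sweep(sweep(z, 2L, sd, "*"), 2L, mu, "+")
  dplyr::bind_cols(tibble::tibble(subject = seq_len(n)), tibble::as_tibble(x))
}

#' Validate a synthetic (or measured) cohort
#'
#' Reports per-parameter skewness (flagging |skewness| > 0.5), the KMO
#' statistic over the combined proximal + distal block, and Bartlett's
#' sphericity p-value.
#'
#' @param data Cohort tibble with n >= 30 subjects.
#' @return List with `skewness` (tibble, with `flagged` column), `kmo`,
#'   `bartlett_p`.
#' @export
validate_cohort <- function(data) {
  stopifnot(nrow(data) >= 30)
  summ <- cohort_summary(data)
  summ$flagged <- abs(summ$skewness) > 0.5
  block <- c(region_parameters("proximal"), region_parameters("distal"))
  corr <- cohort_correlation(data, block)
  list(
    skewness = summ,
    kmo = kmo(corr),
    bartlett_p = bartlett_sphericity(corr, attr(corr, "n"))$p.value
  )
}

#' Draw a single plausible femur parameter set
#'
#' Produces one femur spanning up to about two reference SDs of overall
#' size: a shared isometric size factor scales every length (size dominates
#' real femoral variation), small independent shape jitter perturbs the
#' remaining parameters, and angles/ratios are jittered without scaling.
#' Shaft length and overall length stay geometrically consistent so a
#' derived plate always fits on the shaft.
#'
#' @param seed Integer seed.
#' @param spread Size span in SD units of `H_f` (default 2).
#' @return Named parameter vector over all 29 schema entries.
#' @export
sample_femur_parameters <- function(seed = 1L, spread = 2) {
  set.seed(as.integer(seed))
  stats <- femur_reference_stats()
  mu <- stats::setNames(stats$mean, stats$name)
  sd <- stats::setNames(stats$sd, stats$name)
  schema <- femur_parameter_schema()
  t_size <- stats::runif(1, -spread, spread)
  scale <- 1 + t_size * sd[["H_f"]] / mu[["H_f"]]
  out <- mu
  lengths <- schema$name[schema$unit == "mm"]
  others <- setdiff(schema$name, lengths)
  out[lengths] <- mu[lengths] * scale
  # shape jitter: small for most lengths, frozen for the two parameters that
  # fix the plate/shaft length budget
  jitter_sd <- stats::setNames(0.2 * sd[lengths], lengths)
  jitter_sd[c("H_f", "H_fs")] <- 0
  out[lengths] <- out[lengths] + stats::rnorm(length(lengths), 0, jitter_sd)
  out[others] <- mu[others] + stats::rnorm(length(others), 0, 0.3 * sd[others])
  out
}
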