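#' Prior and convergence configuration for the EM fitters
#'
#' The marker-variance prior is a scaled inverse chi-square,
#' \eqn{\sigma_k^2 \sim \chi^{-2}(\nu, S)}. By default the scale S is sized
#' from the data at fit time, following the convention of the Bayesian
#' whole-genome regression literature: S is set so that the prior marker
#' variance accounts a priori for a fraction `r2` of the phenotypic variance,
#' \deqn{S = (\nu + 1)\, r2\, var(y) / \sum_k var(z_k),}
#' on the working (possibly whitened) scale. A fixed numeric `scale` can be
#' supplied instead. The EM stops when the largest marker-effect change in a
#' sweep falls below `tol * (1 + max|gamma|)`, or at `max_iter` sweeps.
#'
#' @param nu Prior degrees of freedom (> 0). Default 4.
#' @param scale Prior scale S (>= 0), or `NULL` (default) to size it from the
#'   data at fit time.
#' @param r2 A-priori proportion of phenotypic variance attributed to the
#'   markers, used only when `scale` is `NULL`. Default 0.5.
#' @param max_iter Iteration cap. Default 200.
#' @param tol Scale-free convergence tolerance. Default 1e-6.
#'
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(nu = 4, scale = NULL, r2 = 0.5, max_iter = 200L,
                         tol = 1e-6) {
  if (nu <= 0 || (!is.null(scale) && scale < 0) || max_iter < 1 || tol <= 0 ||
      r2 <= 0 || r2 >= 1) {
    abort("need nu > 0, scale >= 0 (or NULL), 0 < r2 < 1, max_iter >= 1, tol > 0.",
          class = "embai_domain_error")
  }
  structure(list(nu = nu, scale = scale, r2 = r2,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "prior_config")
}

# Resolve a data-driven prior scale on the working-scale inputs.
resolve_prior <- function(prior, y, Z) {
  if (!is.null(prior$scale)) return(prior)
  n <- nrow(Z)
  msx <- (sum(Z * Z) - sum(colSums(Z)^2) / n) / (n - 1)
  prior$scale <- (prior$nu + 1) * prior$r2 * var(as.numeric(y)) /
    max(msx, .Machine$double.eps)
  prior
}

#' Conditional posterior expectation of a marker variance (E-step)
#'
#' Replaces the per-marker variance by \eqn{(\hat\gamma_k^2 + S)/(\nu + 1)}.
#' Vectorized over `gamma_k`.
#'
#' @param gamma_k Current marker effect estimate(s).
#' @param prior A [prior_config()] with a resolved (numeric) scale.
#' @return Updated variance(s).
#' @export
e_step_sigma_k <- function(gamma_k, prior = prior_config(scale = 0.01)) {
  if (is.null(prior$scale)) {
    abort("prior scale is unresolved; supply prior_config(scale = ...).",
          class = "embai_domain_error")
  }
  (gamma_k^2 + prior$scale) / (prior$nu + 1)
}

#' Single-marker M-step update
#'
#' The ridge-shrunken regression of the partial residual (the full residual
#' with marker k's contribution added back) on the marker column:
#' \eqn{\hat\gamma_k = z_k^T r_k / (z_k^T z_k + \sigma^2/\hat\sigma_k^2)}.
#'
#' @param z_k Marker column (length n).
#' @param partial_residual Residual vector excluding marker k's contribution.
#' @param sigma_k2 Current marker variance (> 0).
#' @param sigma2 Current residual variance (> 0).
#' @return The updated effect.
#' @export
m_step_gamma_k <- function(z_k, partial_residual, sigma_k2, sigma2) {
  stopifnot(sigma_k2 > 0, sigma2 > 0)
  sum(z_k * partial_residual) / (sum(z_k^2) + sigma2 / sigma_k2)
}

#' Single-covariate M-step update
#'
#' Ordinary least-squares coefficient of the partial residual on one covariate
#' column: \eqn{\hat\alpha_j = w_j^T r_j / (w_j^T w_j)}.
#'
#' @param w_j Covariate column (non-zero norm).
#' @param partial_residual Residual vector excluding covariate j's
#'   contribution.
#' @return The updated coefficient.
#' @export
m_step_alpha <- function(w_j, partial_residual) {
  wtw <- sum(w_j^2)
  if (wtw <= 0) abort("covariate column has zero norm.",
                      class = "embai_domain_error")
  sum(w_j * partial_residual) / wtw
}

#' Residual-variance M-step update
#'
#' \eqn{\hat\sigma^2 = \|r\|^2 / n}, floored at 1e-12 (with a warning) when
#' the fit is numerically exact.
#'
#' @param residual Full residual vector.
#' @param n Sample size.
#' @return The updated residual variance.
#' @export
m_step_sigma2 <- function(residual, n = length(residual)) {
  s2 <- sum(residual^2) / n
  if (s2 < 1e-12) {
    warn("residual variance floored at 1e-12 (near-exact fit).")
    s2 <- 1e-12
  }
  s2
}

# Shared engine behind the BayesA / ridge / spike-and-slab fitters.
em_engine <- function(y, W, Z, prior, method_tag,
                      method_code, pi_init = 0.05, estimate_pi = TRUE,
                      lambda_g = NA_real_, sigma2_reduced = NA_real_,
                      marker_ids = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  W <- W %||% matrix(1, n, 1)
  if (!is.matrix(W)) W <- as.matrix(W)
  if (nrow(W) != n || nrow(Z) != n) {
    abort("dimension mismatch between y, W and Z.", class = "embai_domain_error")
  }
  prior <- resolve_prior(prior, y, Z)
  res <- em_sweep_cpp(y, W, Z, prior$nu, prior$scale, prior$max_iter,
                      prior$tol, method_code, pi_init, estimate_pi)
  if (isTRUE(res$sigma2_floored)) {
    warn("residual variance floored at 1e-12 during EM (near-exact fit).")
  }
  marker_ids <- marker_ids %||% colnames(Z) %||% paste0("m", seq_len(ncol(Z)))
  structure(
    list(
      method_tag = method_tag,
      alpha = drop(res$alpha),
      gamma = stats::setNames(drop(res$gamma), marker_ids),
      sigma_k2 = drop(res$sigma_k2),
      sigma2 = res$sigma2,
      sigma_gamma2 = if (method_code > 0) res$sigma_gamma2 else NA_real_,
      pi = if (method_code == 2) res$pi else NA_real_,
      inclusion = if (method_code == 2)
        stats::setNames(drop(res$inclusion), marker_ids) else NULL,
      lambda_g = lambda_g,
      sigma2_reduced = sigma2_reduced,
      n_iter = res$n_iter,
      converged = res$converged,
      log_posterior_trace = as.numeric(res$trace),
      n = n, q = ncol(Z), c = ncol(W),
      prior = prior
    ),
    class = "embai_fit"
  )
}

#' EM algorithm for BayesA on (possibly whitened) data
#'
#' Fits \eqn{y_c = W_c\alpha + Z_c\gamma + \varepsilon_c} with independent
#' marker effects \eqn{\gamma_k \sim N(0, \sigma_k^2)},
#' \eqn{\sigma_k^2 \sim \chi^{-2}(\nu, S)}. The E-step replaces every
#' \eqn{\sigma_k^2} by its conditional expectation; the M-step maximizes the
#' log-posterior coordinate-wise (marker sweep with an incrementally
#' maintained residual, then covariates, then residual variance).
#'
#' @param data A [whitened_data()] container (raw data may be wrapped with
#'   the identity transform, which is what [fit_emba()] does).
#' @param prior A [prior_config()].
#' @return An `embai_fit` object; see [tidy.embai_fit()] and
#'   [glance.embai_fit()] for tibble views.
#' @export
fit_embayesa <- function(data, prior = prior_config()) {
  stopifnot(inherits(data, "whitened_data"))
  em_engine(data$y_c, data$W_c, data$Z_c, prior,
            method_tag = "emBA", method_code = 0L,
            marker_ids = data$marker_ids)
}

#' Two-stage emBAI fit: whiten the polygenic background, then EM-BayesA
#'
#' Stage one estimates \eqn{\lambda_g} on the reduced model by REML
#' ([estimate_lambda_g()]), builds \eqn{C = (\hat\lambda_g K + I)^{-1/2}}
#' ([build_whitening()]) and transforms y, W and Z. Stage two runs the EM
#' algorithm for BayesA on the whitened data. Marker effects are invariant
#' under the linear transform, so GEBV are computed on the original genotype
#' scale ([predict_gebv()]).
#'
#' @param y Phenotype vector.
#' @param W Fixed-effect design (defaults to an intercept).
#' @param Z A [genotype_matrix()] or dosage matrix.
#' @param K A [kinship_matrix()]; defaults to the VanRaden GRM of `Z`.
#' @param prior A [prior_config()].
#' @return An `embai_fit` with `method_tag = "emBAI"` and the stage-one
#'   `lambda_g` recorded.
#' @export
fit_embai <- function(y, W = NULL, Z, K = NULL, prior = prior_config()) {
  Z <- as_genotype_matrix(Z)
  K <- if (is.null(K)) compute_grm(Z) else as_kinship_matrix(K)
  vr <- estimate_lambda_g(y, W, K)
  op <- build_whitening(K, vr$lambda_g, K_eigen = vr$K_eigen)
  wd <- apply_whitening(op, y, W, Z)
  fit <- em_engine(wd$y_c, wd$W_c, wd$Z_c, prior,
                   method_tag = "emBAI", method_code = 0L,
                   lambda_g = vr$lambda_g, sigma2_reduced = vr$sigma2,
                   marker_ids = wd$marker_ids)
  fit
}

#' EM-BayesA without background whitening (emBA baseline)
#'
#' Identical to [fit_embayesa()] applied to the untransformed data.
#'
#' @inheritParams fit_embai
#' @return An `embai_fit` with `method_tag = "emBA"`.
#' @export
fit_emba <- function(y, W = NULL, Z, prior = prior_config()) {
  Z <- as_genotype_matrix(Z)
  y <- as.numeric(y)
  W <- W %||% matrix(1, length(y), 1)
  fit_embayesa(whitened_data(y, W, Z$dosages, Z$marker_ids), prior)
}

#' Genomic estimated breeding values from a fit
#'
#' \eqn{GEBV_i = \sum_k z_{ik}\hat\gamma_k} on the original (untransformed)
#' dosage scale; fitted values add the covariate contribution
#' \eqn{(W\hat\alpha)_i}.
#'
#' @param fit An `embai_fit`.
#' @param Z The [genotype_matrix()] (or dosage matrix) to predict for.
#' @param W Optional covariate design on the same individuals (defaults to an
#'   intercept column).
#' @return A tibble with columns `id`, `gebv`, `fitted`.
#' @export
predict_gebv <- function(fit, Z, W = NULL) {
  stopifnot(inherits(fit, "embai_fit"))
  Z <- as_genotype_matrix(Z)
  if (Z$q != fit$q) {
    abort("marker count of Z does not match the fit.",
          class = "embai_domain_error")
  }
  W <- W %||% matrix(1, Z$n, 1)
  if (!is.matrix(W)) W <- as.matrix(W)
  if (ncol(W) != fit$c || nrow(W) != Z$n) {
    abort("covariate design does not match the fit.",
          class = "embai_domain_error")
  }
  gebv <- drop(Z$dosages %*% fit$gamma)
  tibble(
    id = rownames(Z$dosages) %||% seq_len(Z$n),
    gebv = gebv,
    fitted = gebv + drop(W %*% fit$alpha)
  )
}

#' @export
print.embai_fit <- function(x, ...) {
  cat("<embai_fit> method = ", x$method_tag,
      ", n = ", x$n, ", q = ", x$q,
      ", iterations = ", x$n_iter,
      if (x$converged) " (converged)" else " (cap reached)", "\n", sep = "")
  if (!is.na(x$lambda_g)) {
    cat("  stage-1 lambda_g = ", sprintf("%.4g", x$lambda_g), "\n", sep = "")
  }
  cat("  sigma2 = ", sprintf("%.4g", x$sigma2),
      ", max |gamma| = ", sprintf("%.4g", max(abs(x$gamma))), "\n", sep = "")
  invisible(x)
}
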