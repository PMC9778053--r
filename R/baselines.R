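#' Spike-and-slab mixture configuration for the BayesC-type fitter
#'
#' @param pi_init Initial marker inclusion probability, in (0, 1); the slab-only
#'   limit `pi_init = 1` (with `estimate_pi = FALSE`) is allowed and reduces the
#'   fit to ridge regression.
#' @param estimate_pi Update the inclusion proportion each iteration as the
#'   mean posterior inclusion probability. Off by default: with a dense
#'   polygenic background the estimated proportion drifts to a degenerate
#'   boundary, so a fixed prior inclusion probability is the standard choice.
#' @return An object of class `mixture_config`.
#' @export
mixture_config <- function(pi_init = 0.05, estimate_pi = FALSE) {
  if (!(pi_init > 0 && pi_init <= 1) || (pi_init == 1 && estimate_pi)) {
    abort("pi_init must be in (0, 1), or exactly 1 with estimate_pi = FALSE.",
          class = "embai_domain_error")
  }
  structure(list(pi_init = pi_init, estimate_pi = isTRUE(estimate_pi)),
            class = "mixture_config")
}

# Optionally run the stage-1 whitening before a baseline fit (background
# control applied to the comparison methods).
baseline_inputs <- function(y, W, Z, whiten, K) {
  Z <- as_genotype_matrix(Z)
  y <- as.numeric(y)
  W <- W %||% matrix(1, length(y), 1)
  if (!is.matrix(W)) W <- as.matrix(W)
  if (!whiten) {
    return(list(data = whitened_data(y, W, Z$dosages, Z$marker_ids),
                lambda_g = NA_real_))
  }
  K <- if (is.null(K)) compute_grm(Z) else as_kinship_matrix(K)
  vr <- estimate_lambda_g(y, W, K)
  op <- build_whitening(K, vr$lambda_g, K_eigen = vr$K_eigen)
  list(data = apply_whitening(op, y, W, Z), lambda_g = vr$lambda_g)
}

#' EM Bayesian ridge regression (emRR baseline)
#'
#' All marker effects share one variance \eqn{\sigma_\gamma^2}. The E-step
#' carries the conditional posterior mean and variance of every effect
#' (\eqn{\hat\gamma_k} and \eqn{v_k = \sigma^2/(z_k^Tz_k +
#' \sigma^2/\sigma_\gamma^2)}); the M-step updates the shared variance as
#' \eqn{(\sum_k (\hat\gamma_k^2 + v_k) + S)/(q + \nu)} and the residual
#' variance with the matching \eqn{\sum_k v_k z_k^Tz_k} correction. The
#' marker sweep is the same single-marker ridge update as BayesA with the
#' common shrinkage ratio \eqn{\sigma^2/\hat\sigma_\gamma^2}.
#'
#' @inheritParams fit_embai
#' @param whiten Apply the stage-1 polygenic whitening before fitting.
#' @param K Kinship for the whitening stage (defaults to the VanRaden GRM of
#'   `Z`); ignored when `whiten = FALSE`.
#' @return An `embai_fit` with `method_tag = "emRR"`.
#' @export
fit_emrr <- function(y, W = NULL, Z, prior = prior_config(),
                     whiten = FALSE, K = NULL) {
  inp <- baseline_inputs(y, W, Z, whiten, K)
  em_engine(inp$data$y_c, inp$data$W_c, inp$data$Z_c, prior,
            method_tag = "emRR", method_code = 1L,
            lambda_g = inp$lambda_g, marker_ids = inp$data$marker_ids)
}

#' EM spike-and-slab (emBC baseline)
#'
#' Each marker effect is a mixture of a point mass at zero and a normal slab
#' with shared variance. The fit is the classic variational EM for Bayesian
#' variable selection: per marker, a conditional Gaussian slab posterior
#' \eqn{N(b_k, v_k)} and a Bernoulli inclusion posterior with log odds
#' \eqn{logit(\pi) + \frac{1}{2}\log(v_k/\sigma_\gamma^2) + b_k^2/(2v_k)};
#' the slab variance is re-estimated from the included posterior mass. The
#' reported `gamma` is the posterior-mean effect \eqn{p_k b_k}.
#'
#' @inheritParams fit_emrr
#' @param mix A [mixture_config()].
#' @return An `embai_fit` with `method_tag = "emBC"`, carrying per-marker
#'   `inclusion` probabilities and the final `pi`.
#' @export
fit_embc <- function(y, W = NULL, Z, prior = prior_config(),
                     mix = mixture_config(), whiten = FALSE, K = NULL) {
  stopifnot(inherits(mix, "mixture_config"))
  inp <- baseline_inputs(y, W, Z, whiten, K)
  em_engine(inp$data$y_c, inp$data$W_c, inp$data$Z_c, prior,
            method_tag = "emBC", method_code = 2L,
            pi_init = mix$pi_init, estimate_pi = mix$estimate_pi,
            lambda_g = inp$lambda_g, marker_ids = inp$data$marker_ids)
}

#' Gaussian maximum-likelihood ridge (emML baseline)
#'
#' The equivalent-GBLUP formulation: y has marginal covariance
#' \eqn{\sigma_\gamma^2 Z Z^T + \sigma^2 I}. The variance ratio
#' \eqn{\theta = \sigma_\gamma^2/\sigma^2} is chosen to maximize the Gaussian
#' marginal likelihood (1-D search on the eigenbasis of \eqn{ZZ^T}, fixed
#' effects profiled by GLS), and the marker effects are recovered as the
#' posterior mean \eqn{\hat\gamma = \theta Z^T (\theta Z Z^T + I)^{-1}
#' (y - W\hat\alpha)}.
#'
#' @inheritParams fit_emrr
#' @return An `embai_fit` with `method_tag = "emML"`; `n_iter` is 1 (direct
#'   maximization, no sweep) and `log_posterior_trace` holds the maximized
#'   marginal log-likelihood.
#' @export
fit_emml <- function(y, W = NULL, Z, prior = prior_config(),
                     whiten = FALSE, K = NULL) {
  inp <- baseline_inputs(y, W, Z, whiten, K)
  d <- inp$data
  n <- d$n
  G <- tcrossprod(d$Z_c)
  eg <- eigen(G, symmetric = TRUE)
  dl <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, d$y_c))
  Wt <- crossprod(eg$vectors, d$W_c)

  # profile ML over alpha and sigma2 given the ratio theta
  prof <- function(theta) {
    v <- theta * dl + 1
    Wv <- Wt / v
    A <- crossprod(Wv, Wt)
    alpha <- solve(A, crossprod(Wv, yt))
    r <- yt - drop(Wt %*% alpha)
    rss <- sum(r^2 / v)
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + sum(log(v)) + n)
    list(ll = ll, alpha = alpha, sigma2 = sigma2)
  }
  opt <- optimize(function(l10) -prof(10^l10)$ll, interval = c(-8, 8),
                  tol = 1e-9)
  cand_theta <- c(10^opt$minimum, 0)
  cand <- lapply(cand_theta, prof)
  best <- which.max(vapply(cand, `[[`, numeric(1), "ll"))
  theta <- cand_theta[best]
  sol <- cand[[best]]

  r0 <- d$y_c - drop(d$W_c %*% sol$alpha)
  v <- theta * dl + 1
  gamma <- theta * drop(crossprod(d$Z_c,
                                  eg$vectors %*% (crossprod(eg$vectors, r0) / v)))
  structure(
    list(
      method_tag = "emML",
      alpha = drop(sol$alpha),
      gamma = stats::setNames(gamma, d$marker_ids),
      sigma_k2 = rep(theta * sol$sigma2, d$q),
      sigma2 = sol$sigma2,
      sigma_gamma2 = theta * sol$sigma2,
      pi = NA_real_, inclusion = NULL,
      lambda_g = inp$lambda_g, sigma2_reduced = NA_real_,
      n_iter = 1L, converged = TRUE,
      log_posterior_trace = sol$ll,
      n = n, q = d$q, c = d$c,
      prior = prior
    ),
    class = "embai_fit"
  )
}

#' EM elastic net (emEN) — not implemented
#'
#' Deliberately unavailable: an elastic-net marker model is outside the scope
#' of this release (it is unreliable on p >> n genomic data, returning
#' degenerate estimates). The function exists so that method dispatch is
#' uniform; it signals a `embai_not_implemented` condition.
#'
#' @inheritParams fit_emrr
#' @export
fit_emen <- function(y, W = NULL, Z, prior = prior_config(),
                     whiten = FALSE, K = NULL) {
  abort("emEN is not implemented in this release.",
        class = "embai_not_implemented")
}

# Uniform dispatcher used by the benchmark driver and the CLI.
fit_method <- function(method, y, W = NULL, Z, K = NULL,
                       prior = prior_config(), mix = mixture_config(),
                       whiten = FALSE) {
  switch(method,
    emBAI = fit_embai(y, W, Z, K = K, prior = prior),
    emBA  = if (whiten) stop("use emBAI for whitened BayesA") else
              fit_emba(y, W, Z, prior = prior),
    emRR  = fit_emrr(y, W, Z, prior = prior, whiten = whiten, K = K),
    emBC  = fit_embc(y, W, Z, prior = prior, mix = mix, whiten = whiten, K = K),
    emML  = fit_emml(y, W, Z, prior = prior, whiten = whiten, K = K),
    emEN  = fit_emen(y, W, Z, prior = prior, whiten = whiten, K = K),
    abort(paste0("unknown method: ", method), class = "embai_domain_error")
  )
}
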