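# Independent oracles used by the property and acceptance tests. These stay
# deliberately naive (direct matrix algebra, generic optimizers, exhaustive
# enumeration) and never share code with the implementation paths they check.

# Restricted log-likelihood of the reduced polygenic model, computed by
# direct matrix inversion (no eigen shortcut), for small n.
oracle_reml_loglik <- function(lambda, y, W, K) {
  n <- length(y)
  cc <- ncol(W)
  H <- lambda * K + diag(n)
  Hi <- solve(H)
  A <- t(W) %*% Hi %*% W
  alpha <- solve(A, t(W) %*% Hi %*% y)
  r <- y - W %*% alpha
  rss <- drop(t(r) %*% Hi %*% r)
  sigma2 <- rss / (n - cc)
  -0.5 * ((n - cc) * log(sigma2) +
            determinant(H, logarithm = TRUE)$modulus[1] +
            determinant(A, logarithm = TRUE)$modulus[1] +
            (n - cc) * (1 + log(2 * pi)))
}

# Golden-section search for the REML-optimal lambda on log10 scale, with an
# explicit boundary comparison at lambda = 0, mirroring the contract of
# estimate_lambda_g but through the direct-inversion objective.
oracle_reml_lambda <- function(y, W, K, lower = -5, upper = 5) {
  f <- function(l10) oracle_reml_loglik(10^l10, y, W, K)
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > 1e-10) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  lam <- 10^((a + b) / 2)
  if (oracle_reml_loglik(0, y, W, K) >= f((a + b) / 2)) lam <- 0
  lam
}

# Marginal log-posterior of the EM-for-BayesA model (marker variances
# integrated out); the quantity whose maximizers the EM fixed points are.
oracle_bayesa_objective <- function(theta, y, W, Z, nu, S) {
  cc <- ncol(W); q <- ncol(Z); n <- length(y)
  alpha <- theta[seq_len(cc)]
  gamma <- theta[cc + seq_len(q)]
  sigma2 <- exp(theta[cc + q + 1])
  r <- y - W %*% alpha - Z %*% gamma
  -0.5 * n * log(sigma2) - sum(r^2) / (2 * sigma2) -
    0.5 * (nu + 1) * sum(log(gamma^2 + S))
}

# Direct numerical maximization of the marginal objective, multi-start.
oracle_bayesa_max <- function(y, W, Z, nu, S, starts) {
  best <- NULL
  for (st in starts) {
    opt <- optim(st, oracle_bayesa_objective, y = y, W = W, Z = Z,
                 nu = nu, S = S, method = "BFGS",
                 control = list(fnscale = -1, maxit = 2000, reltol = 1e-14))
    if (is.null(best) || opt$value > best$value) best <- opt
  }
  best
}

# Exhaustive pairwise AUC: mean over all positive x negative score pairs.
oracle_auc_pairwise <- function(scores, pos_idx) {
  s_pos <- scores[pos_idx]
  s_neg <- scores[-pos_idx]
  tot <- 0
  for (sp in s_pos) tot <- tot + sum(sp > s_neg) + 0.5 * sum(sp == s_neg)
  tot / (length(s_pos) * length(s_neg))
}

# Small labelled dataset with one strong marker, for fitter sanity checks.
make_toy <- function(n = 60, q = 12, effect = 1.2, seed = 99, sd_e = 1) {
  withr::local_seed(seed)
  Z <- matrix(rbinom(n * q, 2, 0.4), n, q)
  while (any(apply(Z, 2, function(x) max(x) == min(x)))) {
    Z <- matrix(rbinom(n * q, 2, 0.4), n, q)
  }
  y <- 5 + effect * Z[, 3] + rnorm(n, 0, sd_e)
  list(y = y, Z = genotype_matrix(Z), qtn = 3L)
}

expect_ascending <- function(fit, slack = 1e-6) {
  tr <- fit$log_posterior_trace
  if (length(tr) >= 2) {
    expect_gte(min(diff(tr)), -slack)
  }
  invisible(fit)
}
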