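#' REML estimate of the polygenic-to-residual variance ratio
#'
#' Stage one of the two-stage fit. On the reduced mixed model
#' \eqn{y = W\alpha + u + \varepsilon} (all marker effects dropped, the marker
#' variance ratio held at zero because most markers are unlinked to the trait),
#' the ratio \eqn{\lambda_g = \sigma^2_g / \sigma^2} is estimated by restricted
#' maximum likelihood. After one eigendecomposition of K every candidate
#' \eqn{\lambda_g} costs O(n), so a 1-D bounded search over
#' \eqn{\log_{10}\lambda_g \in [-5, 5]} is cheap; the boundary
#' \eqn{\hat\lambda_g = 0} is evaluated explicitly and reported when optimal.
#'
#' @param y Numeric phenotype vector (length n).
#' @param W Fixed-effect design matrix (n x c, full column rank). Defaults to
#'   an intercept column.
#' @param K A [kinship_matrix()] (or square matrix).
#'
#' @return A list of class `variance_ratios` with `lambda_g`, `lambda_gamma`
#'   (fixed at 0 in stage one), `sigma2` (REML residual variance at the
#'   optimum), `log_reml`, and the eigendecomposition of K (`K_eigen`) for
#'   reuse by [build_whitening()].
#' @export
estimate_lambda_g <- function(y, W = NULL, K) {
  y <- as.numeric(y)
  n <- length(y)
  W <- W %||% matrix(1, n, 1)
  if (!is.matrix(W)) W <- as.matrix(W)
  cc <- ncol(W)
  if (n <= cc) abort("need more observations than fixed effects.",
                     class = "embai_domain_error")
  if (qr(W)$rank < cc) abort("fixed-effect design is rank deficient.",
                             class = "embai_domain_error")
  K <- as_kinship_matrix(K)
  if (K$n != n) abort("kinship dimension does not match y.",
                      class = "embai_domain_error")

  ek <- eigen(K$values, symmetric = TRUE)
  delta <- pmax(ek$values, 0)

  if (max(delta) - min(delta) < 1e-10 * max(max(delta), 1)) {
    warn("kinship has a flat eigenvalue spectrum (e.g. K = I): lambda_g and sigma2 are not separately identifiable; returning lambda_g = 0.")
    fit0 <- reml_profile(0, crossprod(ek$vectors, y), crossprod(ek$vectors, W),
                         delta, n, cc)
    return(new_variance_ratios(0, fit0$sigma2, fit0$log_reml, ek))
  }

  yt <- drop(crossprod(ek$vectors, y))
  Wt <- crossprod(ek$vectors, W)

  objective <- function(log10_lambda) {
    -reml_profile(10^log10_lambda, yt, Wt, delta, n, cc)$log_reml
  }
  opt <- optimize(objective, interval = c(-5, 5), tol = 1e-8)
  lam_hat <- 10^opt$minimum

  # Plateau guard: sparse major-effect loci (absent from the reduced model)
  # can make the restricted likelihood rise into a flat shelf that extends
  # to the upper search bound. Any "estimate" on that shelf over-whitens
  # (the iid environmental component is modelled away) while being
  # statistically indistinguishable from the shelf's shoulder. When the
  # upper bound's restricted log-likelihood comes within 1.0 units of the
  # optimum — i.e. the data cannot tell the optimum from arbitrarily strong
  # whitening — take the smallest lambda whose restricted log-likelihood is
  # within 1.0 units of the supremum. Well-identified interior optima are
  # untouched.
  ll_hat <- reml_profile(lam_hat, yt, Wt, delta, n, cc)$log_reml
  ll_up <- reml_profile(1e5, yt, Wt, delta, n, cc)$log_reml
  if (ll_up >= ll_hat - 1.0) {
    grid <- 10^seq(-5, 5, by = 0.1)
    ll <- vapply(grid, function(l)
      reml_profile(l, yt, Wt, delta, n, cc)$log_reml, numeric(1))
    ok <- which(ll >= max(ll, ll_hat) - 1.0)
    lam_hat <- grid[ok[1]]
    warn(sprintf(
      "restricted likelihood is flat up to the lambda search bound; taking the smallest statistically equivalent lambda (%.3g).",
      lam_hat))
  }

  cand <- list(
    reml_profile(lam_hat, yt, Wt, delta, n, cc),
    reml_profile(0, yt, Wt, delta, n, cc)
  )
  lam_cand <- c(lam_hat, 0)
  best <- which.max(vapply(cand, `[[`, numeric(1), "log_reml"))
  new_variance_ratios(lam_cand[best], cand[[best]]$sigma2,
                      cand[[best]]$log_reml, ek)
}

# Restricted log-likelihood profiled over alpha and sigma2, on the eigenbasis
# of K. H = lambda*K + I has eigenvalues lambda*delta + 1.
reml_profile <- function(lambda, yt, Wt, delta, n, cc) {
  d <- lambda * delta + 1
  Wd <- Wt / d
  A <- crossprod(Wd, Wt)              # W' H^-1 W
  b <- crossprod(Wd, yt)
  alpha <- solve(A, b)
  r <- yt - drop(Wt %*% alpha)
  rss <- sum(r^2 / d)
  sigma2 <- rss / (n - cc)
  log_reml <- -0.5 * ((n - cc) * log(sigma2) + sum(log(d)) +
                        determinant(A, logarithm = TRUE)$modulus[1] +
                        (n - cc) * (1 + log(2 * pi)))
  list(sigma2 = sigma2, log_reml = log_reml)
}

new_variance_ratios <- function(lambda_g, sigma2, log_reml, K_eigen) {
  structure(
    list(lambda_g = lambda_g, lambda_gamma = 0, sigma2 = sigma2,
         log_reml = log_reml, K_eigen = K_eigen),
    class = "variance_ratios"
  )
}

#' @export
print.variance_ratios <- function(x, ...) {
  cat("<variance_ratios> lambda_g = ", sprintf("%.4g", x$lambda_g),
      ", sigma2 = ", sprintf("%.4g", x$sigma2),
      ", restricted log-lik = ", sprintf("%.4g", x$log_reml), "\n", sep = "")
  invisible(x)
}

#' Build the whitening operator
#'
#' Eigendecomposes \eqn{B = \lambda_g K + I_n = Q \Lambda Q^T} and forms the
#' symmetric inverse square root \eqn{C = Q \Lambda^{-1/2} Q^T}, so that data
#' with covariance \eqn{\sigma^2 B} become homoscedastic and uncorrelated
#' after premultiplication by C. Eigenvalues that come out non-positive by
#' roundoff are floored at 1e-10 with a warning.
#'
#' @param K A [kinship_matrix()] (or square matrix).
#' @param lambda_g Non-negative variance ratio, typically
#'   from [estimate_lambda_g()].
#' @param K_eigen Optional precomputed `eigen()` of K (as returned in
#'   `estimate_lambda_g()$K_eigen`); B shares K's eigenvectors, so this skips
#'   a second decomposition.
#'
#' @return An object of class `whitening_operator` with fields `eigenvalues`,
#'   `eigenvectors`, `transform` (C), `lambda_g`, `b_matrix_hash`.
#' @export
build_whitening <- function(K, lambda_g, K_eigen = NULL) {
  if (lambda_g < 0) abort("lambda_g must be >= 0.", class = "embai_domain_error")
  K <- as_kinship_matrix(K)
  if (is.null(K_eigen)) {
    eb <- eigen(diag(K$n) + lambda_g * K$values, symmetric = TRUE)
    evals <- eb$values
    Q <- eb$vectors
  } else {
    evals <- lambda_g * pmax(K_eigen$values, 0) + 1
    Q <- K_eigen$vectors
  }
  if (min(evals) < -1e-8 * max(evals)) {
    abort("B = lambda_g*K + I is indefinite; K is not positive semi-definite.",
          class = "embai_domain_error")
  }
  if (any(evals < 1e-10)) {
    warn("eigenvalues of B floored at 1e-10.")
    evals <- pmax(evals, 1e-10)
  }
  C <- Q %*% (t(Q) * (1 / sqrt(evals)))
  C <- (C + t(C)) / 2
  structure(
    list(
      eigenvalues = evals,
      eigenvectors = Q,
      transform = C,
      lambda_g = lambda_g,
      b_matrix_hash = rlang::hash(list(lambda_g, K$values))
    ),
    class = "whitening_operator"
  )
}

#' @export
print.whitening_operator <- function(x, ...) {
  cat("<whitening_operator> n = ", nrow(x$transform),
      ", lambda_g = ", sprintf("%.4g", x$lambda_g),
      ", eigenvalue range [", sprintf("%.4g", min(x$eigenvalues)), ", ",
      sprintf("%.4g", max(x$eigenvalues)), "]\n", sep = "")
  invisible(x)
}

#' Apply the whitening transform to phenotype, covariates and genotypes
#'
#' Computes \eqn{y_c = C y}, \eqn{W_c = C W}, \eqn{Z_c = C Z}. If y has
#' covariance \eqn{\sigma^2 B} then \eqn{y_c} has covariance
#' \eqn{\sigma^2 I_n}. Note that a constant column of W (the intercept) is not
#' constant after transformation; its coefficient is unchanged.
#'
#' @param op A [build_whitening()] operator.
#' @param y Phenotype vector.
#' @param W Fixed-effect design (defaults to an intercept column).
#' @param Z A [genotype_matrix()] or dosage matrix.
#'
#' @return An object of class `whitened_data` with `y_c`, `W_c`, `Z_c`,
#'   `marker_ids`, `n`, `q`, `c`.
#' @export
apply_whitening <- function(op, y, W = NULL, Z) {
  stopifnot(inherits(op, "whitening_operator"))
  y <- as.numeric(y)
  n <- length(y)
  W <- W %||% matrix(1, n, 1)
  if (!is.matrix(W)) W <- as.matrix(W)
  Z <- as_genotype_matrix(Z)
  if (nrow(op$transform) != n || nrow(W) != n || Z$n != n) {
    abort("dimension mismatch between whitening operator, y, W and Z.",
          class = "embai_domain_error")
  }
  C <- op$transform
  whitened_data(
    y_c = drop(C %*% y),
    W_c = C %*% W,
    Z_c = C %*% Z$dosages,
    marker_ids = Z$marker_ids
  )
}

#' Construct a whitened-data container
#'
#' Holds the (possibly transformed) phenotype, covariate design and marker
#' matrix that stage two operates on. [fit_embayesa()] accepts either this or
#' raw inputs wrapped with C = I.
#'
#' @param y_c Phenotype vector on the working scale.
#' @param W_c Covariate design matrix.
#' @param Z_c Marker matrix.
#' @param marker_ids Optional marker labels.
#' @return An object of class `whitened_data`.
#' @export
whitened_data <- function(y_c, W_c, Z_c, marker_ids = NULL) {
  y_c <- as.numeric(y_c)
  if (!is.matrix(W_c)) W_c <- as.matrix(W_c)
  stopifnot(nrow(W_c) == length(y_c), nrow(Z_c) == length(y_c))
  structure(
    list(
      y_c = y_c, W_c = W_c, Z_c = Z_c,
      marker_ids = marker_ids %||% colnames(Z_c) %||%
        paste0("m", seq_len(ncol(Z_c))),
      n = length(y_c), q = ncol(Z_c), c = ncol(W_c)
    ),
    class = "whitened_data"
  )
}
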