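test_that("E-step and M-step primitives reproduce their closed forms", {
  expect_equal(e_step_sigma_k(2, prior_config(nu = 4, scale = 1)), 1.0)
  expect_equal(e_step_sigma_k(0, prior_config(nu = 3, scale = 0)), 0.0)
  expect_equal(e_step_sigma_k(0, prior_config(nu = 3, scale = 0.02)), 0.005)
  expect_error(e_step_sigma_k(1, prior_config()), class = "embai_domain_error")

  z <- c(1, -1, 0, 0)
  r_orth <- c(1, 1, 2, -2)          # orthogonal to z
  expect_equal(m_step_gamma_k(z, r_orth, sigma_k2 = 1, sigma2 = 1), 0)
  # vanishing shrinkage recovers the single-marker OLS coefficient
  r2 <- c(3, -1, 1, 1)
  ols <- sum(z * r2) / sum(z^2)
  expect_equal(m_step_gamma_k(z, r2, sigma_k2 = 1e12, sigma2 = 1), ols,
               tolerance = 1e-10)

  w <- rep(1, 4)
  expect_equal(m_step_alpha(w, c(3, 3, 3, 3)), 3)
  expect_equal(m_step_alpha(w, r_orth), mean(r_orth))
  expect_equal(m_step_alpha(c(1, -1, 0, 0), r_orth), 0)
  expect_error(m_step_alpha(rep(0, 4), r_orth), class = "embai_domain_error")

  expect_equal(m_step_sigma2(c(1, -1)), 1.0)
  expect_equal(m_step_sigma2(rep(2, 4)), 4.0)
  expect_warning(s <- m_step_sigma2(rep(0, 5)), regexp = "floored")
  expect_equal(s, 1e-12)
})

test_that("EM fixed point matches brute-force maximization of the marginal posterior", {
  withr::local_seed(8)
  n <- 8; q <- 3
  Z <- matrix(rbinom(n * q, 2, 0.5), n, q)
  Z[, 1] <- c(0, 1, 2, 1, 0, 2, 1, 1)  # ensure polymorphism
  W <- matrix(1, n, 1)
  y <- 2 + 1.5 * Z[, 1] + rnorm(n, 0, 0.4)
  nu <- 4; S <- 0.05
  fit <- fit_embayesa(whitened_data(y, W, Z),
                      prior_config(nu = nu, scale = S, tol = 1e-12,
                                   max_iter = 20000))
  em_theta <- c(fit$alpha, unname(fit$gamma), log(fit$sigma2))
  starts <- list(
    c(mean(y), rep(0, q), log(var(y))),
    c(0, rep(0.5, q), 0),
    em_theta * 0.8 + rnorm(q + 2, 0, 0.05)
  )
  orc <- oracle_bayesa_max(y, W, Z, nu, S, starts)
  # same optimum value and same coordinates
  expect_equal(oracle_bayesa_objective(em_theta, y, W, Z, nu, S),
               orc$value, tolerance = 1e-6)
  expect_equal(em_theta[1:(q + 1)], orc$par[1:(q + 1)], tolerance = 1e-4)
  expect_equal(exp(em_theta[q + 2]), exp(orc$par[q + 2]), tolerance = 1e-4)
})

test_that("the EM objective trace is non-decreasing on representative fits", {
  toy <- make_toy(n = 80, q = 25, seed = 12)
  expect_ascending(fit_emba(toy$y, Z = toy$Z))
  expect_ascending(fit_emrr(toy$y, Z = toy$Z))
  expect_ascending(fit_embc(toy$y, Z = toy$Z))
  dat <- simulate_dataset("multi-qtn", n = 200, q = 800,
                          background_multiplier = 2, seed = 55, n_qtn = 20)
  K <- compute_grm(dat$genotypes)
  expect_ascending(fit_embai(dat$phenotype, Z = dat$genotypes, K = K))
})

test_that("null signal with strong shrinkage leaves all marker effects near zero", {
  withr::local_seed(41)
  n <- 50; q <- 30
  Z <- simulate_genotypes(n, q, 0.2, 0.5, seed = 41)
  W <- matrix(1, n, 1)
  y <- W %*% c(3.2)
  expect_warning(
    fit <- fit_embayesa(whitened_data(drop(y), W, Z$dosages),
                        prior_config(nu = 4, scale = 1e-6)),
    regexp = "floored"
  )
  expect_lt(max(abs(fit$gamma)), 1e-3)
})

test_that("deterministic algorithm is bit-stable across runs", {
  dat <- simulate_dataset("multi-qtn", n = 40, q = 60,
                          background_multiplier = 2, seed = 9, n_qtn = 5)
  K <- compute_grm(dat$genotypes)
  f1 <- fit_embai(dat$phenotype, Z = dat$genotypes, K = K)
  f2 <- fit_embai(dat$phenotype, Z = dat$genotypes, K = K)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$log_posterior_trace, f2$log_posterior_trace)
  expect_identical(f1$lambda_g, f2$lambda_g)
})

test_that("a flat kinship spectrum reduces the two-stage fit to plain EM-BayesA", {
  toy <- make_toy(n = 50, q = 15, seed = 31)
  expect_warning(
    f_two_stage <- fit_embai(toy$y, Z = toy$Z, K = kinship_matrix(diag(50))),
    regexp = "identifiab"
  )
  f_plain <- fit_emba(toy$y, Z = toy$Z)
  expect_equal(f_two_stage$gamma, f_plain$gamma, tolerance = 1e-12)
  expect_equal(f_two_stage$sigma2, f_plain$sigma2, tolerance = 1e-12)
  expect_equal(f_two_stage$lambda_g, 0)
})

test_that("the single QTN carries the largest estimated effect in most replicates", {
  hits <- vapply(1:20, function(s) {
    dat <- simulate_dataset("one-qtn", n = 500, q = 2000,
                            background_multiplier = 2, seed = 7000 + s)
    fit <- fit_emba(dat$phenotype, Z = dat$genotypes)
    which.max(abs(fit$gamma)) == 98
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("marker-effect magnitude is monotone in the prior scale on one marker", {
  withr::local_seed(3)
  n <- 40
  z <- rbinom(n, 2, 0.4)
  y <- 10 + 0.8 * z + rnorm(n, 0, 1)
  Z <- genotype_matrix(matrix(z, ncol = 1))
  gam <- vapply(c(0.001, 0.01, 0.1, 1, 10), function(S) {
    abs(fit_emba(y, Z = Z,
                 prior = prior_config(scale = S, tol = 1e-10,
                                      max_iter = 5000))$gamma[1])
  }, numeric(1))
  # larger prior scale = larger prior marker variance = weaker shrinkage
  expect_true(all(diff(gam) >= -1e-10))
})

test_that("GEBV prediction is the dosage-weighted sum of marker effects", {
  toy <- make_toy(n = 30, q = 5, seed = 61)
  fit <- fit_emba(toy$y, Z = toy$Z)
  pred <- predict_gebv(fit, toy$Z)
  expect_equal(pred$gebv, drop(toy$Z$dosages %*% fit$gamma), tolerance = 1e-12)
  expect_equal(pred$fitted, pred$gebv + fit$alpha, tolerance = 1e-12)
  # zero effects give identically zero GEBV
  fit0 <- fit
  fit0$gamma[] <- 0
  expect_equal(predict_gebv(fit0, toy$Z)$gebv, rep(0, 30))
  # single-marker closed form
  fit1 <- fit
  fit1$gamma <- stats::setNames(c(0.5, 0, 0, 0, 0), names(fit$gamma))
  expect_equal(predict_gebv(fit1, toy$Z)$gebv, 0.5 * toy$Z$dosages[, 1])
  expect_error(predict_gebv(fit, genotype_matrix(toy$Z$dosages[, 1:3])),
               class = "embai_domain_error")
})

test_that("GEBV tracks the genetic component rather than the residual", {
  dat <- simulate_dataset("multi-qtn", n = 300, q = 1000,
                          background_multiplier = 2, seed = 71, n_qtn = 25)
  fit <- fit_emba(dat$phenotype, Z = dat$genotypes)
  pred <- predict_gebv(fit, dat$genotypes)
  expect_gt(cor(pred$gebv, dat$genetic), cor(pred$gebv, dat$residual))
})

test_that("tidy and glance views expose the fit in tabular form", {
  toy <- make_toy(n = 40, q = 8, seed = 81)
  fit <- fit_emba(toy$y, Z = toy$Z)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8)
  expect_named(td, c("marker_id", "gamma_hat", "sigma_k2_hat"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$method, "emBA")
  expect_true(gl$converged %in% c(TRUE, FALSE))
})
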