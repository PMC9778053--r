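test_that("simulated genotypes follow Hardy-Weinberg proportions with MAF in bounds", {
  g <- simulate_genotypes(2000, 10000, 0.1, 0.5, seed = 1)
  expect_true(all(g$dosages %in% 0:2))
  # empirical allele frequencies stay near the drawn interval
  p_hat <- colMeans(g$dosages) / 2
  expect_true(all(p_hat >= 0.05 & p_hat <= 0.55))
  expect_true(all(g$maf > 0 & g$maf <= 0.5))
  # per-column 1-df HWE chi-square, vectorized; at alpha = 0.05 at least 94%
  # of independent HWE columns should be non-significant
  n <- g$n
  n2 <- colSums(g$dosages == 2)
  n1 <- colSums(g$dosages == 1)
  n0 <- n - n1 - n2
  p <- (2 * n2 + n1) / (2 * n)
  e2 <- n * p^2; e1 <- n * 2 * p * (1 - p); e0 <- n * (1 - p)^2
  stat <- (n2 - e2)^2 / e2 + (n1 - e1)^2 / e1 + (n0 - e0)^2 / e0
  frac_ns <- mean(stat < qchisq(0.95, df = 1))
  expect_gte(frac_ns, 0.94)
})

test_that("genotype simulation is reproducible and validates its bounds", {
  g1 <- simulate_genotypes(50, 20, 0.2, 0.4, seed = 7)
  g2 <- simulate_genotypes(50, 20, 0.2, 0.4, seed = 7)
  expect_identical(g1$dosages, g2$dosages)
  g3 <- simulate_genotypes(50, 20, 0.2, 0.4, seed = 8)
  expect_false(identical(g1$dosages, g3$dosages))
  # no monomorphic column survives, even at extreme MAF and small n
  g4 <- simulate_genotypes(6, 200, 0.1, 0.1, seed = 3)
  expect_true(all(apply(g4$dosages, 2, function(x) max(x) > min(x))))
  expect_error(simulate_genotypes(2, 1, 0.6, 0.7, seed = 1),
               class = "embai_domain_error")
  expect_error(simulate_genotypes(2, 1, 0, 0.5, seed = 1),
               class = "embai_domain_error")
  expect_error(simulate_genotypes(1, 5, 0.1, 0.5, seed = 1),
               class = "embai_domain_error")
})

test_that("HWE genotype frequencies converge to 1/4, 1/2, 1/4 at p = 0.5", {
  counts <- c(`0` = 0, `1` = 0, `2` = 0)
  for (s in 1:300) {
    g <- simulate_genotypes(4, 1, 0.5, 0.5, seed = s)
    tab <- table(factor(g$dosages, levels = 0:2))
    counts <- counts + as.numeric(tab)
  }
  freq <- counts / sum(counts)
  expect_equal(unname(freq), c(0.25, 0.5, 0.25), tolerance = 0.1)
})

test_that("single-QTN scenario places the QTN at marker 98 with the target variance", {
  g <- simulate_genotypes(300, 200, 0.1, 0.5, seed = 5)
  sc <- make_scenario_one_qtn(300, 200, background_multiplier = 0, seed = 5,
                              genotypes = g)
  expect_identical(sc$qtn_indices, 98L)
  # with no polygenic term: QTN variance = h2/(1-h2) * sigma2_e = 10/9
  v_real <- sc$qtn_effects^2 * var(g$dosages[, 98])
  expect_equal(v_real, 10 / 9, tolerance = 1e-10)
  expect_error(make_scenario_one_qtn(300, 97, 0, seed = 5),
               class = "embai_domain_error")
  # closed form: effect = sqrt(target variance / realized marker variance)
  expect_equal(sc$qtn_effects, sqrt((10 / 9) / var(g$dosages[, 98])),
               tolerance = 1e-10)
})

test_that("realized single-QTN PVE matches the heritability convention", {
  dat <- simulate_dataset("one-qtn", n = 2000, q = 10000,
                          background_multiplier = 2, seed = 7)
  pve <- var(dat$genetic) /
    (var(dat$genetic) + var(dat$polygenic) + var(dat$residual))
  expect_equal(pve, 0.1, tolerance = 0.03)
  expect_equal(mean(dat$phenotype), 10, tolerance = 0.5)
})

test_that("multi-QTN scenarios sample eligible markers and split variance equally", {
  g <- simulate_genotypes(400, 1500, 0.1, 0.5, seed = 11)
  sc <- make_scenario_multi_qtn(400, 1500, background_multiplier = 0, seed = 11,
                                genotypes = g)
  expect_length(sc$qtn_indices, 50)
  expect_true(all(g$maf[sc$qtn_indices] > 0.3))
  # total genetic variance: pve/(1-pve) * sigma2_e = 10, split equally
  vz <- apply(g$dosages[, sc$qtn_indices], 2, var)
  expect_equal(sum(sc$qtn_effects^2 * vz), 10, tolerance = 1e-8)
  expect_equal(max(sc$qtn_effects^2 * vz), min(sc$qtn_effects^2 * vz),
               tolerance = 1e-8)
  expect_error(
    make_scenario_multi_qtn(400, 1500, 0, seed = 11, genotypes = g,
                            maf_min = 0.499),
    class = "embai_domain_error"
  )
})

test_that("realized multi-QTN PVE averages its target across seeds", {
  pves <- vapply(1:20, function(s) {
    dat <- simulate_dataset("multi-qtn", n = 500, q = 2000,
                            background_multiplier = 0, seed = s)
    var(dat$genetic) / var(dat$phenotype)
  }, numeric(1))
  expect_equal(mean(pves), 0.5, tolerance = 0.05)
})

test_that("phenotype decomposition is exact and reproducible", {
  g <- simulate_genotypes(200, 500, 0.1, 0.5, seed = 21)
  sc <- make_scenario_multi_qtn(200, 500, background_multiplier = 2, seed = 21,
                                genotypes = g, n_qtn = 10)
  d1 <- simulate_phenotype(g, sc)
  d2 <- simulate_phenotype(g, sc)
  expect_identical(d1$phenotype, d2$phenotype)
  recon <- sc$mu + d1$genetic + d1$polygenic + d1$residual
  expect_identical(d1$phenotype, recon)
  # zero multiplier means an exactly zero polygenic component
  sc0 <- make_scenario_multi_qtn(200, 500, background_multiplier = 0, seed = 21,
                                 genotypes = g, n_qtn = 10)
  d0 <- simulate_phenotype(g, sc0)
  expect_identical(d0$polygenic, rep(0, 200))
})

test_that("polygenic draws through an explicit kinship respect its covariance contract", {
  g <- simulate_genotypes(100, 300, 0.1, 0.5, seed = 31)
  sc <- make_scenario_one_qtn(100, 300, background_multiplier = 2, seed = 31,
                              genotypes = g)
  K <- compute_grm(g)
  d <- simulate_phenotype(g, sc, kinship = K)
  expect_identical(d$phenotype,
                   sc$mu + d$genetic + d$polygenic + d$residual)
  expect_error(simulate_phenotype(g, sc, kinship = kinship_matrix(diag(5))),
               class = "embai_domain_error")
})

test_that("null-scenario phenotypic variance is calibrated to the residual variance", {
  vars <- means <- numeric(100)
  for (s in 1:100) {
    g <- simulate_genotypes(60, 40, 0.1, 0.5, seed = 5000 + s)
    sc <- make_scenario_multi_qtn(60, 40, background_multiplier = 0,
                                  seed = 5000 + s, genotypes = g, n_qtn = 0)
    d <- simulate_phenotype(g, sc)
    vars[s] <- var(d$phenotype)
    means[s] <- mean(d$phenotype)
  }
  # sample variance of y should sit within 3 standard errors of sigma2_e = 10
  se <- sd(vars) / sqrt(100)
  expect_lt(abs(mean(vars) - 10), 3 * se)
  expect_equal(mean(means), 10, tolerance = 0.2)
})

test_that("genotype matrix construction validates entries and computes MAF", {
  m <- matrix(c(0, 1, 2, 2, 2, 2), nrow = 3)
  expect_error(genotype_matrix(m), NA)
  gm <- genotype_matrix(m)
  expect_equal(gm$maf, c(m1 = 0.5, m2 = 0), tolerance = 1e-12)
  expect_error(genotype_matrix(matrix(c(0, 1, 3, 2), 2)),
               class = "embai_domain_error")
  expect_error(genotype_matrix(matrix(c(0, NA, 1, 2), 2)),
               class = "embai_domain_error")
})
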