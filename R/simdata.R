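#' Construct a genotype matrix object
#'
#' Wraps an n x q allele-dosage matrix (entries 0, 1, 2) together with marker
#' ids and per-marker minor allele frequencies. All model-fitting functions in
#' the package accept this object (or a bare dosage matrix, which is coerced).
#'
#' @param dosages Numeric matrix, individuals in rows, markers in columns,
#'   every entry in \{0, 1, 2\}. Column names, when present, become marker ids.
#' @param marker_ids Optional character vector of marker labels (length q).
#'
#' @return An object of class `genotype_matrix` with fields `dosages`,
#'   `marker_ids`, `maf`, `n`, `q`.
#' @export
genotype_matrix <- function(dosages, marker_ids = NULL) {
  if (!is.matrix(dosages) || !is.numeric(dosages)) {
    abort("`dosages` must be a numeric matrix.", class = "embai_domain_error")
  }
  if (nrow(dosages) < 2L || ncol(dosages) < 1L) {
    abort("need at least 2 individuals and 1 marker.", class = "embai_domain_error")
  }
  if (anyNA(dosages)) {
    abort("genotype dosages must all be 0, 1 or 2 (impute missing values first).",
          class = "embai_domain_error")
  }
  rng <- range(dosages)
  if (rng[1] < 0 || rng[2] > 2 || any(dosages != floor(dosages))) {
    abort("genotype dosages must all be 0, 1 or 2 (impute missing values first).",
          class = "embai_domain_error")
  }
  storage.mode(dosages) <- "double"
  marker_ids <- marker_ids %||% colnames(dosages) %||%
    paste0("m", seq_len(ncol(dosages)))
  if (length(marker_ids) != ncol(dosages)) {
    abort("`marker_ids` length must equal the number of marker columns.",
          class = "embai_domain_error")
  }
  colnames(dosages) <- marker_ids
  p_hat <- colMeans(dosages) / 2
  structure(
    list(
      dosages = dosages,
      marker_ids = marker_ids,
      maf = pmin(p_hat, 1 - p_hat),
      n = nrow(dosages),
      q = ncol(dosages)
    ),
    class = "genotype_matrix"
  )
}

as_genotype_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) x else genotype_matrix(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", x$n, " individuals x ", x$q, " markers; MAF range [",
      sprintf("%.3f", min(x$maf)), ", ", sprintf("%.3f", max(x$maf)), "]\n",
      sep = "")
  invisible(x)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws q independent markers. For each marker an allele frequency is drawn
#' uniformly on \[`maf_low`, `maf_high`\] and n dosages are drawn from the
#' Hardy-Weinberg genotype probabilities p^2, 2p(1-p), (1-p)^2 (equivalently
#' Binomial(2, p)). Monomorphic columns are redrawn so every marker is
#' polymorphic in sample.
#'
#' @param n Number of individuals (>= 2).
#' @param q Number of markers (>= 1).
#' @param maf_low,maf_high Bounds of the uniform allele-frequency distribution,
#'   0 < `maf_low` <= `maf_high` <= 0.5.
#' @param seed Integer seed; the result is reproducible given the seed.
#'
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, q, maf_low = 0.1, maf_high = 0.5, seed = 1L) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    abort("MAF bounds must satisfy 0 < maf_low <= maf_high <= 0.5.",
          class = "embai_domain_error")
  }
  if (n < 2L || q < 1L) {
    abort("need n >= 2 and q >= 1.", class = "embai_domain_error")
  }
  withr::local_seed(seed)
  p <- runif(q, maf_low, maf_high)
  Z <- matrix(rbinom(n * q, 2L, rep(p, each = n)), nrow = n, ncol = q)
  # polymorphism is required downstream (MAF invariant, GRM scaling)
  repeat {
    mono <- which(matrixStats_colConstant(Z))
    if (length(mono) == 0L) break
    Z[, mono] <- rbinom(n * length(mono), 2L, rep(p[mono], each = n))
  }
  genotype_matrix(Z, marker_ids = paste0("m", seq_len(q)))
}

# constant column <=> zero column variance, via two vectorized passes
matrixStats_colConstant <- function(Z) {
  n <- nrow(Z)
  m1 <- colSums(Z) / n
  m2 <- colSums(Z * Z) / n
  (m2 - m1 * m1) <= 0
}

#' Define the single-QTN simulation scenario
#'
#' One quantitative trait nucleotide (QTN) at a fixed marker position (the
#' 98th), with a prescribed heritability. The additive effect size is solved
#' from the realized variance of the QTN column so that
#' \deqn{h^2 = \sigma^2_{QTN} / (\sigma^2_{QTN} + \sigma^2_g + \sigma^2_e),}
#' i.e. \eqn{\sigma^2_{QTN} = h^2/(1-h^2)\,(\sigma^2_g + \sigma^2_e)}, with the
#' polygenic variance \eqn{\sigma^2_g} set to `background_multiplier` times the
#' residual variance.
#'
#' @param n,q Sample size and marker count for the scenario.
#' @param background_multiplier Polygenic background multiplier m, so that
#'   \eqn{\sigma^2_g = m\,\sigma^2_e}. Typical values 2, 5, 10; 0 disables the
#'   polygenic term.
#' @param seed Integer seed; also seeds the internally simulated genotypes when
#'   `genotypes` is not supplied.
#' @param genotypes Optional [genotype_matrix()] the scenario will be used
#'   with; needed to solve the effect size from the realized marker variance.
#' @param qtn_index Position of the QTN (default 98).
#' @param h2 QTN heritability (default 0.1).
#' @param mu Population mean (default 10).
#' @param sigma2_e Residual variance (default 10).
#'
#' @return An object of class `sim_scenario`.
#' @export
make_scenario_one_qtn <- function(n, q, background_multiplier, seed = 1L,
                                  genotypes = NULL, qtn_index = 98L,
                                  h2 = 0.1, mu = 10, sigma2_e = 10) {
  if (q < qtn_index) {
    abort(paste0("q must be at least ", qtn_index, " to place the QTN."),
          class = "embai_domain_error")
  }
  genotypes <- genotypes %||%
    simulate_genotypes(n, q, 0.1, 0.5, seed = derive_seed(seed, 101L))
  stopifnot(genotypes$n == n, genotypes$q == q)
  sigma2_g <- background_multiplier * sigma2_e
  v_qtn <- h2 / (1 - h2) * (sigma2_g + sigma2_e)
  vz <- var(genotypes$dosages[, qtn_index])
  effect <- sqrt(v_qtn / vz)
  new_scenario(
    n = n, q = q, qtn_indices = qtn_index, qtn_effects = effect,
    mu = mu, sigma2_e = sigma2_e,
    background_multiplier = background_multiplier, seed = seed,
    experiment = "one-qtn"
  )
}

#' Define the multi-QTN simulation scenario
#'
#' `n_qtn` QTNs are sampled uniformly among markers with minor allele
#' frequency above `maf_min`, each carrying an equal share of the total genetic
#' variance implied by `total_pve` (randomly signed):
#' \eqn{\sigma^2_{QTN,total} = PVE/(1-PVE)\,(\sigma^2_g + \sigma^2_e)}.
#'
#' @inheritParams make_scenario_one_qtn
#' @param n_qtn Number of QTNs (default 50).
#' @param total_pve Total proportion of phenotypic variance explained by all
#'   QTNs jointly (default 0.5).
#' @param maf_min QTN eligibility threshold on MAF (default 0.3).
#'
#' @return An object of class `sim_scenario`.
#' @export
make_scenario_multi_qtn <- function(n, q, background_multiplier, seed = 1L,
                                    genotypes = NULL, n_qtn = 50L,
                                    total_pve = 0.5, maf_min = 0.3,
                                    mu = 10, sigma2_e = 10) {
  genotypes <- genotypes %||%
    simulate_genotypes(n, q, 0.1, 0.5, seed = derive_seed(seed, 101L))
  stopifnot(genotypes$n == n, genotypes$q == q)
  eligible <- which(genotypes$maf > maf_min)
  if (length(eligible) < n_qtn) {
    abort(sprintf("only %d markers have MAF > %.2f; %d QTNs requested.",
                  length(eligible), maf_min, n_qtn),
          class = "embai_domain_error")
  }
  sigma2_g <- background_multiplier * sigma2_e
  v_total <- total_pve / (1 - total_pve) * (sigma2_g + sigma2_e)
  v_each <- v_total / n_qtn
  withr::local_seed(derive_seed(seed, 202L))
  idx <- sort(sample(eligible, n_qtn))
  vz <- apply(genotypes$dosages[, idx, drop = FALSE], 2, var)
  effects <- sqrt(v_each / vz) * sample(c(-1, 1), n_qtn, replace = TRUE)
  new_scenario(
    n = n, q = q, qtn_indices = idx, qtn_effects = effects,
    mu = mu, sigma2_e = sigma2_e,
    background_multiplier = background_multiplier, seed = seed,
    experiment = "multi-qtn"
  )
}

new_scenario <- function(n, q, qtn_indices, qtn_effects, mu, sigma2_e,
                         background_multiplier, seed, experiment) {
  stopifnot(!anyDuplicated(qtn_indices), all(qtn_indices >= 1),
            all(qtn_indices <= q), length(qtn_indices) == length(qtn_effects))
  structure(
    list(
      n = n, q = q,
      qtn_indices = as.integer(qtn_indices),
      qtn_effects = as.double(qtn_effects),
      mu = mu, sigma2_e = sigma2_e,
      background_multiplier = background_multiplier,
      seed = as.integer(seed),
      experiment = experiment
    ),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> ", x$experiment, ": n=", x$n, ", q=", x$q, ", ",
      length(x$qtn_indices), " QTN(s), mu=", x$mu, ", sigma2_e=", x$sigma2_e,
      ", background x", x$background_multiplier, ", seed=", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Simulate a phenotype from a scenario
#'
#' Builds \eqn{y = \mu 1 + Z_{QTN}\gamma + u + \varepsilon} with
#' \eqn{u \sim MVN(0, \sigma^2_g K)} and
#' \eqn{\varepsilon \sim N(0, \sigma^2_e I)}. When `kinship` is `NULL` the
#' polygenic term is drawn through the VanRaden factorisation of the genomic
#' relationship matrix of `genotypes` (u = M b with iid normal b), which has
#' exactly the covariance \eqn{\sigma^2_g\,GRM} without forming K. All
#' components are stored so the phenotype decomposition can be reconstructed
#' exactly.
#'
#' @param genotypes A [genotype_matrix()] matching the scenario dimensions.
#' @param scenario A `sim_scenario` from [make_scenario_one_qtn()] or
#'   [make_scenario_multi_qtn()].
#' @param kinship Optional [kinship_matrix()] used to draw the polygenic term;
#'   defaults to the (implicit) VanRaden GRM of `genotypes`.
#'
#' @return An object of class `sim_dataset` with fields `genotypes`,
#'   `phenotype`, `genetic` (the QTN contribution), `polygenic`, `residual`,
#'   `truth` (the scenario).
#' @export
simulate_phenotype <- function(genotypes, scenario, kinship = NULL) {
  genotypes <- as_genotype_matrix(genotypes)
  if (genotypes$n != scenario$n || genotypes$q != scenario$q) {
    abort("genotype dimensions do not match the scenario.",
          class = "embai_domain_error")
  }
  n <- scenario$n
  sigma2_g <- scenario$background_multiplier * scenario$sigma2_e
  withr::local_seed(derive_seed(scenario$seed, 303L))
  genetic <- drop(genotypes$dosages[, scenario$qtn_indices, drop = FALSE] %*%
                    scenario$qtn_effects)
  if (sigma2_g == 0) {
    u <- rep(0, n)
  } else if (is.null(kinship)) {
    p <- colMeans(genotypes$dosages) / 2
    Mc <- sweep(genotypes$dosages, 2, 2 * p)
    cnorm <- 2 * sum(p * (1 - p))
    u <- drop(Mc %*% rnorm(genotypes$q, sd = sqrt(sigma2_g / cnorm)))
  } else {
    kinship <- as_kinship_matrix(kinship)
    if (kinship$n != n) {
      abort("kinship dimension does not match the scenario.",
            class = "embai_domain_error")
    }
    ek <- eigen(kinship$values, symmetric = TRUE)
    lam <- pmax(ek$values, 0)
    if (min(ek$values) < -1e-8 * max(abs(ek$values))) {
      abort("kinship matrix is not positive semi-definite.",
            class = "embai_domain_error")
    }
    u <- drop(ek$vectors %*% (sqrt(sigma2_g * lam) * rnorm(n)))
  }
  eps <- rnorm(n, sd = sqrt(scenario$sigma2_e))
  y <- scenario$mu + genetic + u + eps
  structure(
    list(
      genotypes = genotypes,
      phenotype = y,
      genetic = genetic,
      polygenic = u,
      residual = eps,
      truth = scenario
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> n=", length(x$phenotype), ", q=", x$genotypes$q,
      "; var(y)=", sprintf("%.2f", var(x$phenotype)), "\n", sep = "")
  print(x$truth)
  invisible(x)
}
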