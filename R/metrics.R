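#' Mean squared error
#'
#' @param y Observed values.
#' @param y_hat Predicted values (same length).
#' @return Mean of squared differences.
#' @export
mse <- function(y, y_hat) {
  check_equal_length(y, y_hat)
  mean((y - y_hat)^2)
}

#' Mean absolute error
#'
#' @inheritParams mse
#' @return Mean of absolute differences.
#' @export
mae <- function(y, y_hat) {
  check_equal_length(y, y_hat)
  mean(abs(y - y_hat))
}

#' Pearson correlation between observed and predicted values
#'
#' The standard sample correlation (cross-products normalized by the n-1
#' sample standard deviations). Errors on constant input, where the
#' correlation is undefined.
#'
#' @inheritParams mse
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(y, y_hat) {
  check_equal_length(y, y_hat)
  if (length(y) < 2L) abort("need at least 2 observations.",
                            class = "embai_domain_error")
  if (sd(y) == 0 || sd(y_hat) == 0) {
    abort("correlation undefined for a constant vector.",
          class = "embai_undefined_metric")
  }
  stats::cor(y, y_hat)
}

check_equal_length <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) == 0L) {
    abort("vectors must have equal, nonzero length.",
          class = "embai_domain_error")
  }
  invisible(TRUE)
}

#' AUC for recovering QTN positions from estimated marker effects
#'
#' Markers at the true QTN indices are labelled positive, all others
#' negative; the score is the absolute estimated effect. The area under the
#' ROC curve is computed by the rank (Mann-Whitney) statistic with ties
#' averaged, i.e. P(score_pos > score_neg) + P(tie)/2.
#'
#' @param gamma_hat Length-q vector of estimated marker effects.
#' @param qtn_indices Integer positions (1-based) of the true QTNs;
#'   must leave at least one negative marker.
#' @return AUC in \[0, 1\].
#' @export
coefficient_auc <- function(gamma_hat, qtn_indices) {
  q <- length(gamma_hat)
  qtn_indices <- as.integer(qtn_indices)
  if (length(qtn_indices) < 1L || length(qtn_indices) >= q ||
      any(qtn_indices < 1L) || any(qtn_indices > q)) {
    abort("need 1 <= #positives < q with indices in [1, q].",
          class = "embai_undefined_metric")
  }
  score <- abs(gamma_hat)
  rk <- rank(score)               # ties averaged
  n_pos <- length(qtn_indices)
  n_neg <- q - n_pos
  (sum(rk[qtn_indices]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Score a fit against observed phenotypes and (optionally) simulation truth
#'
#' Computes the evaluation indicators in one tibble row: MSE and MAE of the
#' fitted phenotypes, Pearson correlation between phenotype and GEBV, and —
#' when the true QTN positions are known — the coefficient AUC.
#'
#' @param fit An `embai_fit`.
#' @param genotypes The [genotype_matrix()] the fit is evaluated on.
#' @param y Observed phenotype vector.
#' @param W Optional covariate design (defaults to an intercept).
#' @param qtn_indices Optional true QTN positions for the AUC.
#' @return A one-row tibble: `method`, `mse`, `mae`, `pearson_r`, `auc`,
#'   `n_iter`, `converged`, `lambda_g`.
#' @export
evaluate_fit <- function(fit, genotypes, y, W = NULL, qtn_indices = NULL) {
  pred <- predict_gebv(fit, genotypes, W)
  tibble(
    method = fit$method_tag,
    mse = mse(y, pred$fitted),
    mae = mae(y, pred$fitted),
    pearson_r = pearson_r(y, pred$gebv),
    auc = if (is.null(qtn_indices)) NA_real_ else
      coefficient_auc(fit$gamma, qtn_indices),
    n_iter = fit$n_iter,
    converged = fit$converged,
    lambda_g = fit$lambda_g
  )
}
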