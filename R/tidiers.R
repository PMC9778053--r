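#' Tidy a fitted marker-effect model
#'
#' One row per marker: the estimated effect, its prior-posterior variance and,
#' for the spike-and-slab fit, the posterior inclusion probability.
#'
#' @param x An `embai_fit`.
#' @param ... Unused.
#' @return A tibble with columns `marker_id`, `gamma_hat`, `sigma_k2_hat`
#'   (and `inclusion` for emBC).
#' @export
tidy.embai_fit <- function(x, ...) {
  out <- tibble(
    marker_id = names(x$gamma),
    gamma_hat = unname(x$gamma),
    sigma_k2_hat = x$sigma_k2
  )
  if (!is.null(x$inclusion)) out$inclusion <- unname(x$inclusion)
  out
}

#' One-row model summary of a fitted marker-effect model
#'
#' @param x An `embai_fit`.
#' @param ... Unused.
#' @return A one-row tibble: method, dimensions, stage-one `lambda_g` (NA for
#'   unwhitened fits), residual variance, iteration count, convergence flag,
#'   final objective value and prior settings.
#' @export
glance.embai_fit <- function(x, ...) {
  tibble(
    method = x$method_tag,
    n = x$n, q = x$q,
    lambda_g = x$lambda_g,
    sigma2 = x$sigma2,
    sigma_gamma2 = x$sigma_gamma2,
    pi = x$pi,
    n_iter = x$n_iter,
    converged = x$converged,
    log_posterior = x$log_posterior_trace[length(x$log_posterior_trace)],
    prior_nu = x$prior$nu,
    prior_scale = x$prior$scale
  )
}

#' Plot the per-iteration objective trace of an EM fit
#'
#' @param fit An `embai_fit`.
#' @return A ggplot object.
#' @export
plot_trace <- function(fit) {
  stopifnot(inherits(fit, "embai_fit"))
  df <- tibble(iteration = seq_along(fit$log_posterior_trace),
               log_posterior = fit$log_posterior_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$log_posterior)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "EM iteration", y = "log-posterior objective",
                  title = fit$method_tag) +
    ggplot2::theme_bw()
}

#' Plot estimated marker effects along the genome
#'
#' @param fit An `embai_fit`.
#' @param qtn_indices Optional true QTN positions to highlight.
#' @return A ggplot object.
#' @export
plot_effects <- function(fit, qtn_indices = NULL) {
  stopifnot(inherits(fit, "embai_fit"))
  df <- tidy(fit)
  df$position <- seq_len(nrow(df))
  df$qtn <- df$position %in% (qtn_indices %||% integer())
  ggplot2::ggplot(df, ggplot2::aes(.data$position, abs(.data$gamma_hat),
                                   colour = .data$qtn)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = if (is.null(qtn_indices)) "none"
                                         else "legend") +
    ggplot2::labs(x = "marker", y = "|estimated effect|", colour = "QTN",
                  title = fit$method_tag) +
    ggplot2::theme_bw()
}
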