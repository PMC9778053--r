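#' Simulate one complete dataset for a scenario cell
#'
#' Convenience wrapper: simulates genotypes, builds the scenario (solving QTN
#' effects from the realized marker variances) and draws the phenotype, all
#' from one replicate seed.
#'
#' @param experiment `"one-qtn"` or `"multi-qtn"`.
#' @param n,q Sample size and marker count.
#' @param background_multiplier Polygenic multiplier m (\eqn{\sigma^2_g = m\,\sigma^2_e}).
#' @param seed Integer replicate seed.
#' @param ... Passed on to [make_scenario_one_qtn()] /
#'   [make_scenario_multi_qtn()] (e.g. `h2`, `n_qtn`, `total_pve`).
#' @return A `sim_dataset`.
#' @export
simulate_dataset <- function(experiment = c("multi-qtn", "one-qtn"),
                             n, q = 10000L, background_multiplier = 2,
                             seed = 1L, ...) {
  experiment <- match.arg(experiment)
  g <- simulate_genotypes(n, q, 0.1, 0.5, seed = derive_seed(seed, 101L))
  sc <- switch(experiment,
    "one-qtn" = make_scenario_one_qtn(n, q, background_multiplier,
                                      seed = seed, genotypes = g, ...),
    "multi-qtn" = make_scenario_multi_qtn(n, q, background_multiplier,
                                          seed = seed, genotypes = g, ...)
  )
  simulate_phenotype(g, sc)
}

#' Define a scenario-grid benchmark
#'
#' The full factorial of sample sizes by polygenic-background multipliers,
#' with a fixed number of replicates per cell.
#'
#' @param sample_sizes Vector of sample sizes (e.g. `c(500, 1000, 2000)`).
#' @param background_multipliers Vector of multipliers (e.g. `c(2, 5, 10)`).
#' @param n_replicates Replicates per cell (>= 1).
#' @param experiment `"one-qtn"` or `"multi-qtn"`.
#' @param q Marker count (default 10000).
#' @return An object of class `benchmark_grid`.
#' @export
benchmark_grid <- function(sample_sizes, background_multipliers,
                           n_replicates = 10L,
                           experiment = c("multi-qtn", "one-qtn"),
                           q = 10000L) {
  experiment <- match.arg(experiment)
  if (length(sample_sizes) < 1L || length(background_multipliers) < 1L ||
      n_replicates < 1L) {
    abort("grid must be non-empty with n_replicates >= 1.",
          class = "embai_domain_error")
  }
  structure(
    list(sample_sizes = sample_sizes,
         background_multipliers = background_multipliers,
         n_replicates = as.integer(n_replicates),
         experiment = experiment, q = as.integer(q)),
    class = "benchmark_grid"
  )
}

#' Run the scenario-grid benchmark
#'
#' For every cell (sample size x background multiplier) and replicate:
#' simulate a dataset, fit every requested method, and score it with
#' [evaluate_fit()]. Replicate seeds are derived deterministically from the
#' master seed and the cell coordinates, so results are independent of grid
#' ordering. Replicate-level failures are caught, reported, and excluded.
#'
#' @param grid A [benchmark_grid()].
#' @param methods Character vector among `"emBAI"`, `"emBA"`, `"emRR"`,
#'   `"emBC"`, `"emML"`.
#' @param seed Master integer seed.
#' @param prior A [prior_config()] shared by all fits.
#' @param mix A [mixture_config()] for the spike-and-slab fitter.
#' @param verbose Print per-cell progress.
#' @return A tibble of class `embai_benchmark`: one row per cell x replicate
#'   x method with the metric columns of [evaluate_fit()].
#' @export
run_benchmark <- function(grid, methods = c("emBAI", "emBA", "emRR"),
                          seed = 1L, prior = prior_config(),
                          mix = mixture_config(), verbose = FALSE) {
  stopifnot(inherits(grid, "benchmark_grid"))
  cells <- expand.grid(n = grid$sample_sizes, m = grid$background_multipliers)
  rows <- list()
  n_failed <- 0L
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n[ci]; m <- cells$m[ci]
    for (rep_i in seq_len(grid$n_replicates)) {
      rep_seed <- derive_seed(seed, n, round(100 * m), rep_i)
      dat <- tryCatch(
        simulate_dataset(grid$experiment, n = n, q = grid$q,
                         background_multiplier = m, seed = rep_seed),
        error = function(e) e
      )
      if (inherits(dat, "error")) {
        warn(sprintf("replicate failed to simulate (n=%d, m=%g, rep=%d): %s",
                     n, m, rep_i, conditionMessage(dat)))
        n_failed <- n_failed + 1L
        next
      }
      K <- NULL
      if ("emBAI" %in% methods) K <- compute_grm(dat$genotypes)
      for (method in methods) {
        row <- tryCatch({
          fit <- fit_method(method, y = dat$phenotype, Z = dat$genotypes,
                            K = K, prior = prior, mix = mix)
          ev <- evaluate_fit(fit, dat$genotypes, dat$phenotype,
                             qtn_indices = dat$truth$qtn_indices)
          dplyr::mutate(ev, n = n, background_multiplier = m,
                        replicate = rep_i, seed = rep_seed, .before = 1)
        }, error = function(e) e)
        if (inherits(row, "error")) {
          warn(sprintf("fit failed (%s, n=%d, m=%g, rep=%d): %s",
                       method, n, m, rep_i, conditionMessage(row)))
          n_failed <- n_failed + 1L
        } else {
          rows[[length(rows) + 1L]] <- row
        }
      }
      if (verbose) {
        message(sprintf("cell n=%d m=%g replicate %d/%d done",
                        n, m, rep_i, grid$n_replicates))
      }
    }
  }
  if (n_failed > 0L) warn(sprintf("%d replicate fit(s) failed and were excluded.",
                                  n_failed))
  out <- dplyr::bind_rows(rows)
  class(out) <- c("embai_benchmark", class(out))
  attr(out, "grid") <- grid
  out
}

#' Aggregate a benchmark table to cell means and standard errors
#'
#' @param results An `embai_benchmark` tibble from [run_benchmark()].
#' @return A tibble with one row per method x cell: means and standard errors
#'   of each metric and the replicate count.
#' @export
summarize_benchmark <- function(results) {
  results |>
    dplyr::group_by(.data$method, .data$n, .data$background_multiplier) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(
        c("mse", "mae", "pearson_r", "auc", "n_iter"),
        list(mean = ~mean(.x, na.rm = TRUE),
             se = ~sd(.x, na.rm = TRUE) / sqrt(sum(!is.na(.x))))
      ),
      .groups = "drop"
    )
}

#' Plot benchmark metrics by scenario cell
#'
#' One panel per metric, methods in colour, sample size on the x axis,
#' faceted by the polygenic-background multiplier.
#'
#' @param object An `embai_benchmark` tibble.
#' @param metrics Which metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embai_benchmark <- function(object,
                                     metrics = c("pearson_r", "auc"), ...) {
  long <- object |>
    dplyr::select(dplyr::all_of(c("method", "n", "background_multiplier",
                                  metrics))) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$n), y = .data$value,
                                     colour = .data$method)) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2,
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                          width = 0.2,
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_grid(metric ~ background_multiplier, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size", y = NULL, colour = "method") +
    ggplot2::theme_bw()
}
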