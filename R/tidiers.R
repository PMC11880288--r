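# broom-style tidiers and ggplot2 methods for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an optimizer run
#'
#' `tidy()` returns the per-iteration best-fitness trace; `glance()` a
#' one-row summary with the test metrics and decoded configuration.
#'
#' @param x A `gleo_run` from [run_optimizer()], [grid_search_ht()] or
#'   [baseline_rfr()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gleo_run <- function(x, ...) {
  dplyr::mutate(x$trace, algorithm = x$algorithm, mode = x$mode,
                .before = 1)
}

#' @rdname tidy.gleo_run
#' @export
glance.gleo_run <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    mode = x$mode,
    n_selected = length(x$best_mask),
    n_trees = x$best_config$n_trees,
    m_trees = x$best_config$m_trees,
    min_leaf_size = x$best_config$min_leaf_size,
    n_splits = x$best_config$n_splits,
    best_fitness = x$best_fitness,
    train_rmse = x$train_metrics$rmse,
    test_rmse = x$test_metrics$rmse,
    test_r2 = x$test_metrics$r2,
    test_slope = x$test_metrics$slope,
    n_train = x$n_train,
    n_test = x$n_test
  )
}

#' Plot the convergence trace of an optimizer run
#'
#' @param object A `gleo_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gleo_run <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$iter, .data$best_rmse)) +
    ggplot2::geom_step(linewidth = 0.6, colour = "#2c5f8a") +
    ggplot2::labs(
      x = "Iteration", y = "Best validation RMSE",
      title = sprintf("%s-RFR-%s convergence", object$algorithm,
                      gsub("_", "-", object$mode))
    ) +
    ggplot2::theme_minimal()
}

#' Measured-vs-predicted calibration plot
#'
#' Scatter of predicted against measured torque on a row subset, with the
#' identity line and the fitted calibration slope.
#'
#' @param run A `gleo_run`.
#' @param table The feature table the run was made from.
#' @param rows Row indices to plot (e.g. the test subset).
#' @return A ggplot.
#' @export
plot_calibration <- function(run, table, rows = seq_len(nrow(table))) {
  sub <- table[rows, , drop = FALSE]
  d <- tibble::tibble(measured = sub$Torque,
                      predicted = predict(run$fit, sub))
  s <- metric_slope(d$measured, d$predicted)
  ggplot2::ggplot(d, ggplot2::aes(.data$measured, .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "#2c5f8a") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2462e", linewidth = 0.6) +
    ggplot2::labs(x = "Measured torque (scaled)",
                  y = "Predicted torque (scaled)",
                  title = sprintf("Calibration slope %.3f", s)) +
    ggplot2::theme_minimal()
}

#' Plot a binned grey-relational profile
#'
#' @param profile Output of [binned_grd_profile()].
#' @return A ggplot.
#' @export
plot_grd_profile <- function(profile) {
  d <- dplyr::filter(profile, .data$count > 0)
  ggplot2::ggplot(d, ggplot2::aes((.data$lo + .data$hi) / 2, .data$grd)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$count), width = 0.018) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Torque bin centre", y = "Mean GRD",
                  fill = "Windows") +
    ggplot2::theme_minimal()
}
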