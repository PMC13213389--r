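#' Tidy a p-Laplacian solution
#'
#' One row per vertex: index, labeled flag, pinned value (`NA` when
#' unlabeled) and prediction.
#'
#' @param x A `plap_solution`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy plap_solution
#' @export
tidy.plap_solution <- function(x, ...) {
  tibble::tibble(
    vertex = seq_along(x$u), labeled = x$labeled, g = x$g, u = x$u
  )
}

#' One-row summary of a p-Laplacian solution
#'
#' @param x A `plap_solution`.
#' @param ... Unused.
#' @return Tibble with p, alpha, sizes and convergence diagnostics.
#' @method glance plap_solution
#' @export
glance.plap_solution <- function(x, ...) {
  tibble::tibble(
    p = x$p, alpha = x$alpha, n = length(x$u), n_labeled = sum(x$labeled),
    iterations = x$iterations, residual = x$residual, tol = x$tol,
    converged = x$converged
  )
}

#' Plot label efficiency: error versus training fraction
#'
#' Averages a results table over runs and folds (and, by default, picks the
#' best `(p, k)` cell per training fraction) and draws mean RMSE% against
#' the training percentage, one line per model variant.
#'
#' @param results A results tibble.
#' @param best If `TRUE` (default) plot the per-training-fraction optimum
#'   over `(p, k)`; otherwise plot all cells.
#' @return A ggplot object.
#' @export
plot_label_efficiency <- function(results, best = TRUE) {
  agg <- if (best) best_cells(results) else aggregate_results(results)
  ggplot2::ggplot(agg, ggplot2::aes(
    x = .data$training_percent, y = .data$mean_rmse_percent,
    colour = .data$variant, group = .data$variant
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(
      ggplot2::vars(.data$target), ggplot2::vars(.data$dataset)
    ) +
    ggplot2::labs(
      x = "Training %", y = "Mean RMSE (%)", colour = "variant"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the large-p profile of the error
#'
#' Mean RMSE% against p (log scale), one line per neighbour count, to
#' visualise convergence of the solution family as p grows.
#'
#' @param sweep Output of [asymptotic_sweep()].
#' @return A ggplot object.
#' @export
plot_p_profile <- function(sweep) {
  sweep <- dplyr::filter(sweep, is.finite(.data$p))
  ggplot2::ggplot(sweep, ggplot2::aes(
    x = .data$p, y = .data$mean_rmse_percent,
    colour = factor(.data$k), group = .data$k
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "p", y = "Mean RMSE (%)", colour = "k") +
    ggplot2::theme_minimal()
}

#' @method autoplot plap_results
#' @export
autoplot.plap_results <- function(object, ...) {
  plot_label_efficiency(object, ...)
}
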