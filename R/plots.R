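#' Plot stability-selection performance curves
#'
#' Mean test-set accuracy, precision and recall against the number of
#' retained features, with +/- 1 SD ribbons across permutations.
#'
#' @param x A `stability_result` (or list of them, overlaid by combo).
#' @param metrics Metrics to facet (default all three).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_stability_curves <- function(x, metrics = c("accuracy", "precision", "recall"),
                                  ...) {
  results <- if (inherits(x, "stability_result")) list(x) else x
  long <- bind_rows(purrr::map(results, tidy)) |>
    tidyr::pivot_longer(cols = -c("combo", "task", "k"),
                        names_to = c("metric", "stat"),
                        names_pattern = "(.*)_(mean|sd)") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value") |>
    filter(.data$metric %in% metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$mean,
                                     colour = .data$combo, fill = .data$combo)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = pmin(.data$mean + .data$sd, 1)),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "number of features (k)", y = "mean over permutations",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_stability_curves
#' @param object A `stability_result`.
#' @export
autoplot.stability_result <- function(object, ...) {
  plot_stability_curves(object, ...)
}

#' Plot the top-15 occurrence matrix
#'
#' Heat-map-style tile plot of the percentage of permutations in which each
#' feature ranked among the top predictors, one column per run.
#'
#' @param results Named list of `stability_result` objects (names label the
#'   columns), or a single result.
#' @return A ggplot object.
#' @export
plot_occurrence <- function(results) {
  if (inherits(results, "stability_result")) {
    results <- setNames(list(results),
                        paste(results$task, results$combo, sep = "/"))
  }
  long <- bind_rows(purrr::map2(results, names(results),
                                ~ mutate(.x$occurrence, run = .y)))
  long$feature <- factor(long$feature, levels = rev(results[[1]]$occurrence$feature))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run, y = .data$feature,
                                     fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "% of\npermutations") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot logistic coefficient ranking
#'
#' Bar graph of the signed ridge-logistic coefficients of the z-scored
#' features; positive bars are positively associated with the class-1 group.
#'
#' @param ranking A `logistic_ranking` from [logistic_rank()].
#' @return A ggplot object.
#' @export
plot_logistic_rank <- function(ranking) {
  df <- as_tibble(ranking)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coefficient, y = .data$feature,
                                   fill = .data$coefficient > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "logistic regression coefficient (z-scored input)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_logistic_rank
#' @param object A `logistic_ranking`.
#' @param ... Unused.
#' @export
autoplot.logistic_ranking <- function(object, ...) plot_logistic_rank(object)
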