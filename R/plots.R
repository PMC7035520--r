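#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   labs scale_x_log10 theme_minimal
NULL

#' Plot a screening result
#'
#' Lollipop chart of composite CYP scores for the retained compounds, in
#' descending score order.
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, ...) {
  ranked <- rank_compounds(object)
  ranked$compound_id <- factor(ranked$compound_id, levels = rev(ranked$compound_id))
  ggplot(ranked, aes(x = .data$score, y = .data$compound_id)) +
    ggplot2::geom_segment(aes(x = 0, xend = .data$score, yend = .data$compound_id),
                          color = "grey60") +
    geom_point(color = "steelblue") +
    labs(x = "Composite CYP-inhibition score", y = NULL,
         title = "Retained compounds by composite score") +
    theme_minimal()
}

#' Plot a fitted dose-response curve
#'
#' Observed percent-inhibition points and the fitted four-parameter
#' log-logistic curve on a log-dose axis, with the IC50 marked.
#'
#' @param object A converged `dose_response_fit`.
#' @param n_curve Number of points for the smooth curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, n_curve = 200, ...) {
  if (!object$converged) abort_validation("Cannot plot a non-converged fit.")
  rng <- range(object$data$dose)
  grid <- tibble(dose = exp(seq(log(rng[1]), log(rng[2]), length.out = n_curve)))
  grid$response <- predict(object, grid)
  ggplot(object$data, aes(x = .data$dose, y = .data$response)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, color = "firebrick") +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed",
                        color = "grey40") +
    scale_x_log10() +
    labs(x = "Dose (µg/mL)", y = "Inhibition (%)",
         title = sprintf("IC50 = %.3g µg/mL", object$ic50)) +
    theme_minimal()
}

#' Plot quadrant fractions
#'
#' Bar chart of the four gated population fractions.
#'
#' @param object A `quadrant_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quadrant_summary
#' @export
autoplot.quadrant_summary <- function(object, ...) {
  labels <- c(Q1 = "Q1 late apoptotic", Q2 = "Q2 necrotic",
              Q3 = "Q3 viable", Q4 = "Q4 early apoptotic")
  df <- dplyr::mutate(as_tibble(object), label = labels[.data$quadrant])
  ggplot(df, aes(x = .data$label, y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Fraction of events") +
    theme_minimal()
}

#' Degree distribution of a network
#'
#' Histogram of node degrees per role, with the hub threshold marked.
#'
#' @param network A `bipartite_network`.
#' @param hub_min_degree Threshold line to draw (default 10).
#' @return A ggplot.
#' @export
plot_degree_distribution <- function(network, hub_min_degree = 10) {
  deg <- degree_map(network)
  ggplot(deg, aes(x = .data$degree)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = hub_min_degree - 0.5, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::facet_wrap(~ role, scales = "free_y") +
    labs(x = "Degree", y = "Nodes") +
    theme_minimal()
}
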