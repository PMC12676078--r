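#' Ordination plot of a principal coordinates analysis
#'
#' @param object A [pcoa()] result.
#' @param colour_by Optional vector (aligned with samples) to colour
#'   points by, e.g. genotype or an environment variable.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rhizo_pcoa <- function(object, colour_by = NULL, ...) {
  df <- tidy(object)
  pos <- object$values[object$values > 0]
  pct <- 100 * pos[1:2] / sum(pos)
  if (!is.null(colour_by)) df$colour_by <- colour_by
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pct[1]),
                  y = sprintf("PCo2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) p + ggplot2::geom_point(alpha = 0.8)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour_by),
                               alpha = 0.8) +
    ggplot2::labs(colour = NULL)
}

#' Variance-explained bars for a (forward-selected) dbRDA model
#'
#' Stacked bar of the share of community variation attributed to each
#' selected historic-environment variable, after conditioning.
#'
#' @param object A `dbrda_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dbrda_fit <- function(object, ...) {
  df <- tidy(object)
  if (!nrow(df)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No variables selected"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = "model", y = 100 * .data$R2,
                                   fill = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Variation explained (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Reaction norms of the microbial effect in the two nitrogen
#' environments
#'
#' Points are per-genotype microbial effects; lines are the ordinary
#' least-squares reaction norms whose slopes the simulation test
#' compares.
#'
#' @param object A `slope_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.slope_comparison <- function(object, ...) {
  est <- object$estimates
  est$x <- object$x[est$genotype]
  ggplot2::ggplot(est, ggplot2::aes(.data$x, .data$me,
                                    colour = .data$glasshouse_n)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = object$predictor, y = "Microbial effect",
                  colour = "Glasshouse N",
                  subtitle = sprintf("slope difference p = %.3g",
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Diversity metric against a historic-environment variable
#'
#' Per-sample points with the mixed-model slope from
#' [fit_env_diversity_model()].
#'
#' @param data Per-sample tibble with the metric and environment columns.
#' @param response Metric column name.
#' @param env Environment column name.
#' @param fit Optional `env_metric_fit` to annotate with.
#' @return A ggplot.
#' @export
plot_metric_vs_env <- function(data, response, env, fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(.data[[env]], .data[[response]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::labs(subtitle = sprintf("slope %.3g, p = %.3g",
                                              fit$slope, fit$p_value))
  }
  p
}
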