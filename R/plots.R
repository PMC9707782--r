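#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed risk ratios against the permutation null
#'
#' Observed log risk ratios with their Wald confidence intervals, overlaid
#' on the permutation-null highest-density intervals; a shift is supported
#' where the two intervals do not overlap.
#'
#' @param object A `btk_nocturnality` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.btk_nocturnality <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$hpdi_low, ymax = .data$hpdi_high,
                   colour = "null HPDI"),
      linewidth = 4, alpha = 0.4) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$rr, ymin = .data$ci_low, ymax = .data$ci_high,
                   colour = "observed RR")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c("null HPDI" = "grey40", "observed RR" = "#2166ac"),
      name = NULL) +
    ggplot2::labs(x = NULL, y = "log risk ratio of nocturnality",
                  title = "Nocturnality shift vs. wild baseline") +
    ggplot2::theme_minimal()
}

#' Plot fixed-effect estimates of a fitted model
#'
#' Coefficients (excluding the intercept) with Wald 95 percent intervals,
#' on the standardized-covariate scale so effect sizes are comparable.
#'
#' @param object A `btk_zinb` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.btk_zinb <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "(Intercept)", ]
  z <- stats::qnorm(0.975)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$term,
                                                     .data$estimate),
                                  y = .data$estimate)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$estimate - z * .data$std_error,
                   ymax = .data$estimate + z * .data$std_error)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "standardized effect on log detection rate",
                  title = object$spec$name) +
    ggplot2::theme_minimal()
}

#' Plot monthly detection rates
#'
#' Mean monthly detection rate across sites, coloured by season — the
#' standard seasonal habitat-use summary.
#'
#' @param site_months Tibble from [detection_rate()].
#' @return A ggplot.
#' @export
plot_detection_rates <- function(site_months) {
  stopifnot("rate" %in% names(site_months))
  d <- site_months |>
    dplyr::group_by(.data$month, .data$season) |>
    dplyr::summarise(rate = mean(.data$rate, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$month, y = .data$rate,
                                  fill = .data$season)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean monthly detection rate",
                  fill = "season") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a candidate-model comparison
#'
#' Within-set AICc differences by hypothesis set, annotated with Akaike
#' weights.
#'
#' @param comparison Tibble from [compare_models()].
#' @return A ggplot.
#' @export
plot_model_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$within_delta + .data$between_delta,
                               y = stats::reorder(.data$model,
                                                  -(.data$within_delta +
                                                      .data$between_delta)),
                               colour = .data$set)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("w=%.2f", .data$weight)),
                       nudge_x = 0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = expression(Delta * "AICc from overall best"),
                  y = NULL, colour = "hypothesis set") +
    ggplot2::theme_minimal()
}
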