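# ggplot2 visualisations for each result type.

#' Plot test-set performance of validated EpiScores
#'
#' Dot-and-interval plot of out-of-sample Pearson correlations with their
#' 95% confidence intervals, ordered by correlation strength, one colour per
#' test cohort. The dashed line marks the selection threshold.
#'
#' @param object An `episcore_validation` table from [evaluate_episcores()].
#' @param r_threshold Selection threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.episcore_validation <- function(object, r_threshold = 0.1, ...) {
  object |>
    dplyr::mutate(episcore_id = stats::reorder(.data$episcore_id, .data$pearson_r)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$pearson_r, y = .data$episcore_id,
                                 colour = .data$cohort)) +
    ggplot2::geom_vline(xintercept = r_threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.25) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Test-set Pearson r (95% CI)", y = NULL,
                  colour = "Test set") +
    ggplot2::theme_minimal()
}

#' Forest plot of EpiScore-disease hazard ratios
#'
#' @param object An `association_table` from [run_association_grid()].
#' @param stage Model stage to display (default `"full"`).
#' @param only_nested Restrict to associations passing the nested filter.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.association_table <- function(object, stage = "full",
                                       only_nested = TRUE, ...) {
  dat <- object[object$stage == stage & object$status == "ok", ]
  if (only_nested && "passes_nested" %in% names(dat)) {
    dat <- dat[dat$passes_nested %in% TRUE, ]
  }
  dat |>
    dplyr::mutate(label = paste(.data$episcore_id, .data$disease, sep = " → "),
                  label = stats::reorder(.data$label, .data$hazard_ratio)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$hazard_ratio, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.25) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio per 1-SD score (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cross-validation curve of an elastic-net penalty path
#'
#' @param object An `enet_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object: mean CV error with one-SE ribbon against
#'   log lambda, with the chosen penalty marked.
#' @export
autoplot.enet_cv <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = log(.data$lambda), y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - .data$std.error,
                                      ymax = .data$estimate + .data$std.error),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$chosen_lambda),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = expression(log(lambda)), y = "Mean CV squared error") +
    ggplot2::theme_minimal()
}

#' Hazard-ratio stability across follow-up truncation horizons
#'
#' @param data Output of [followup_truncation()].
#' @return A ggplot object.
#' @export
plot_truncation <- function(data) {
  dat <- data[data$status == "ok", ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$horizon, y = .data$hazard_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Follow-up truncated at (years)",
                  y = "Hazard ratio (95% CI)") +
    ggplot2::theme_minimal()
}
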