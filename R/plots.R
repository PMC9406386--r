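#' Plot a time-intensity curve with its extracted parameters
#'
#' @param curve A curve tibble.
#' @param params Optional one-row tibble from [extract_parameters()]; when
#'   given, baseline, onset, maximum and the half-maximum crossing are
#'   annotated.
#' @return A ggplot object.
#' @export
plot_curve <- function(curve, params = NULL) {
  curve <- validate_curve(curve)
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = .data$time_s, y = .data$intensity_au)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "luminance (AU)") +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    p <- p +
      ggplot2::geom_hline(yintercept = params$baseline, linetype = "dashed",
                          colour = "steelblue") +
      ggplot2::geom_hline(yintercept = params$baseline + params$fmax,
                          linetype = "dashed", colour = "firebrick") +
      ggplot2::geom_vline(xintercept = params$t_onset, linetype = "dotted") +
      ggplot2::geom_vline(xintercept = params$t_onset + params$tmax,
                          linetype = "dotted", colour = "firebrick") +
      ggplot2::geom_point(
        data = tibble::tibble(time_s = params$t_onset + params$t_half,
                              intensity_au = params$baseline + params$fmax / 2),
        colour = "darkorange", size = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve plot
#'
#' @param object An `icg_roc`.
#' @param ... Unused.
#' @return A ggplot object of the ROC curve with the chance diagonal.
#' @method autoplot icg_roc
#' @export
autoplot.icg_roc <- function(object, ...) {
  pts <- object$points |>
    dplyr::arrange(1 - .data$specificity, .data$sensitivity)
  df <- dplyr::bind_rows(
    tibble::tibble(fpr = 0, sensitivity = 0),
    tibble::tibble(fpr = 1 - pts$specificity, sensitivity = pts$sensitivity),
    tibble::tibble(fpr = 1, sensitivity = 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Per-group parameter distribution plot
#'
#' @param params Parameter tibble with a `group` column.
#' @param parameter Which parameter to plot (default `"slope"`).
#' @return A ggplot object (points + group means).
#' @export
plot_group_parameter <- function(params, parameter = "slope") {
  stopifnot(parameter %in% names(params), "group" %in% names(params))
  ggplot2::ggplot(params,
                  ggplot2::aes(x = .data$group,
                               y = .data[[parameter]])) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, colour = "grey40") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = parameter) +
    ggplot2::theme_minimal()
}
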