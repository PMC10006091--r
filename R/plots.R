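# Chart figures; every plot draws only from objects that are also serialised
# in the study summary.

#' Individuals control chart figure
#'
#' x chart with CL and LCL lines, flagged points highlighted; optionally
#' the moving-range chart below.
#'
#' @param chart a [control_limits()] result.
#' @return a ggplot object.
#' @export
plot_control_chart <- function(chart) {
  stopifnot(inherits(chart, "control_chart"))
  df <- data.frame(i = seq_along(chart$x), x = chart$x,
                   flagged = seq_along(chart$x) %in% chart$flagged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$x)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged), show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::geom_hline(yintercept = chart$cl, linetype = "solid", colour = "blue") +
    ggplot2::geom_hline(yintercept = chart$lcl, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "plan (acquisition order)", y = "percent gamma value",
                  title = sprintf("x chart: CL %.2f, LCL %.2f", chart$cl, chart$lcl)) +
    ggplot2::theme_minimal()
}

#' ROC curve figure
#'
#' @param roc a [roc_auc()] result.
#' @return a ggplot object.
#' @export
plot_roc <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::theme_minimal()
}

#' Profile comparison figure
#'
#' Measured vs calculated dose along a line with the per-point absolute
#' gamma on a secondary panel-style overlay.
#'
#' @param profile a [profile_compare()] result.
#' @return a ggplot object.
#' @export
plot_profile <- function(profile) {
  scale <- max(profile$calculated) / max(2, max(profile$gamma, na.rm = TRUE))
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$calculated, colour = "calculated")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured, colour = "measured"), size = 0.8) +
    ggplot2::geom_col(ggplot2::aes(y = .data$gamma * scale), alpha = 0.3, width = 0.8) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "absolute gamma")
    ) +
    ggplot2::labs(x = "position along line (mm)", y = "dose", colour = NULL) +
    ggplot2::theme_minimal()
}
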