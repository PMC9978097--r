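# ggplot2 views of the fitted objects: the per-variant scatter with method
# fit lines, and the leave-one-out forest plot.

#' Scatter plot of instrument effects with per-method fit lines
#'
#' Plots each instrument's exposure effect against its outcome effect with
#' error bars of one standard error, overlaying the fitted causal slope of
#' each estimator (IVW and the other methods through the origin, MR-Egger
#' with its intercept).
#'
#' @param call An `mr_call` with estimates.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(call) {
  if (is.null(call$estimates)) {
    abort_mr("Call is not testable; nothing to plot.", "mrflow_usage_error")
  }
  d <- tibble::as_tibble(call$instruments)
  pleio <- call$sensitivity$pleiotropy
  lines <- dplyr::mutate(
    call$estimates[, c("method", "beta")],
    intercept = ifelse(.data$method == "mr_egger", pleio$intercept, 0)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gamma, y = .data$Gamma)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$Gamma - .data$se_Gamma,
                   ymax = .data$Gamma + .data$se_Gamma),
      width = 0, colour = "grey60"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$gamma - .data$se_gamma,
                   xmax = .data$gamma + .data$se_gamma),
      height = 0, colour = "grey60"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$beta, intercept = .data$intercept,
                   colour = .data$method)
    ) +
    ggplot2::labs(
      x = "Effect on exposure", y = "Effect on outcome", colour = "Method",
      title = sprintf("%s → %s", call$exposure_label, call$outcome_label)
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of leave-one-out estimates
#'
#' One row per left-out instrument showing the re-estimated IVW effect and
#' 95% confidence interval, with the all-instrument estimate at the bottom.
#'
#' @param call An `mr_call` with estimates.
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(call) {
  if (is.null(call$sensitivity)) {
    abort_mr("Call is not testable; nothing to plot.", "mrflow_usage_error")
  }
  d <- call$sensitivity$leave_one_out
  d$left_out <- factor(d$left_out, levels = rev(d$left_out))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$left_out)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$influential)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "IVW estimate (leaving one variant out)", y = NULL,
                  title = sprintf("%s → %s", call$exposure_label,
                                  call$outcome_label)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_mr_scatter
#' @param object An `mr_call`.
#' @param type `"scatter"` or `"leave_one_out"`.
#' @param ... Unused.
#' @export
autoplot.mr_call <- function(object, type = c("scatter", "leave_one_out"),
                             ...) {
  type <- match.arg(type)
  switch(type,
    scatter = plot_mr_scatter(object),
    leave_one_out = plot_leave_one_out(object)
  )
}
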