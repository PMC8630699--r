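#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param owsa An [one_way_sa()] result.
#' @param base_icer Baseline ICER drawn as the reference line; defaults to
#'   the base case at default parameters.
#' @param top Number of parameters to show (by span).
#' @return A ggplot object.
#' @export
plot_tornado <- function(owsa, base_icer = NULL, top = 12) {
  if (is.null(base_icer))
    base_icer <- run_base_case()$incremental$icer_qaly
  df <- utils::head(as.data.frame(owsa), top)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       y = .data$label, yend = .data$label),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A [run_psa()] result.
#' @return A ggplot object showing the probability that the combination arm
#'   is cost-effective across willingness-to-pay values.
#' @export
plot_ceac <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  ggplot2::ggplot(psa$ceac, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "P(combination cost-effective)") +
    ggplot2::theme_minimal()
}
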