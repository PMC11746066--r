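#' Cost-effectiveness plane scatter with confidence ellipse and WTP line
#'
#' Per-iteration incremental (QALY, cost) points of the comparator versus
#' the reference, the 95\% confidence ellipse of their joint distribution,
#' and the willingness-to-pay line through the origin (points below the line
#' are cost-effective at that threshold).
#'
#' @param psa A `tki_psa`.
#' @param reference,comparator Strategy names.
#' @param wtp Willingness-to-pay threshold (slope of the dashed line).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, reference, comparator, wtp) {
  d <- psa_deltas(psa, reference, comparator)
  el <- ellipse_points(confidence_ellipse(psa, reference, comparator))
  ggplot2::ggplot(d, ggplot2::aes(x = de, y = dc)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.35, size = 0.8, colour = "steelblue4") +
    ggplot2::geom_path(data = el, colour = "firebrick") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Incremental QALYs (%s vs %s)", comparator, reference),
      y = "Incremental cost (US$)",
      title = sprintf("Cost-effectiveness plane, WTP $%s/QALY",
                      format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param ceac_df A `tki_ceac` data frame from [ceac()].
#' @param wtp Optional threshold to mark with a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df, wtp = NULL) {
  p <- ggplot2::ggplot(ceac_df,
                       ggplot2::aes(x = wtp, y = probability,
                                    colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (US$/QALY)",
                  y = "Probability cost-effective", colour = "Strategy") +
    ggplot2::theme_minimal()
  if (!is.null(wtp))
    p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = "dashed")
  p
}

#' Tornado diagram
#'
#' Horizontal bars from the ICER at each parameter's low bound to the ICER
#' at its high bound, widest spread on top, with the base-case ICER marked.
#'
#' @param dsa A `tki_dsa` from [tornado()].
#' @param top Number of parameters to show (default 15).
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa, top = 15) {
  d <- utils::head(as.data.frame(dsa), top)
  d$id <- factor(d$id, levels = rev(d$id))
  ggplot2::ggplot(d, ggplot2::aes(y = id)) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_low,
                                       xend = icer_high,
                                       yend = id),
                          linewidth = 4, colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = attr(dsa, "base_icer"),
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("ICER, %s vs %s (US$/QALY)", attr(dsa, "comparator"),
                  attr(dsa, "reference")),
      y = NULL) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("de", "dc", "wtp", "probability", "strategy",
                          "id", "icer_low", "icer_high"))
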