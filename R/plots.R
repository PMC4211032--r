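#' Plot the two-way sensitivity grid
#'
#' Heatmap of incremental net benefit over per-visit leisure cost and
#' mobile effectiveness; cells favoring in-person follow-up (negative
#' INB) show in red.
#'
#' @param object A `cea_twoway` from [two_way()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cea_twoway <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$leisure_cost_per_visit),
                               y = factor(.data$mobile_effect),
                               fill = .data$inb)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$inb)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(x = "Patient lost leisure time per visit (CAD)",
                  y = "Mobile-arm success probability",
                  fill = "INB (CAD)",
                  title = "Incremental net benefit, mobile vs in-person") +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param object A `cea_ceac` from [ceac()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda,
                                       y = .data$p_preferred)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay per effect (CAD)",
                  y = "P(mobile follow-up preferred)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot the ICER plane of PSA draws
#'
#' Scatter of per-draw incremental effect (x) against incremental cost
#' (y), intervention minus comparator, with the origin marked. Draws in
#' the lower half are cost-saving for the mobile arm.
#'
#' @param object A `cea_icer_plane` from [icer_plane()], or a `cea_psa`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cea_icer_plane <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_effect,
                                       y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7, color = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Incremental effect (mobile - in-person)",
                  y = "Incremental cost, CAD (mobile - in-person)",
                  title = "ICER plane, probabilistic sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cea_icer_plane
#' @export
autoplot.cea_psa <- function(object, ...) {
  autoplot.cea_icer_plane(icer_plane(object), ...)
}
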