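# ggplot2 views of the three result types: cohort occupancy over age,
# the incremental cloud on the cost-effectiveness plane, the
# acceptability curve, and the tornado diagram.

#' Plot cohort occupancy over age
#'
#' @param object A `cess_trace`.
#' @param ... Unused.
#' @return A ggplot: stacked occupancy of the smoker, former-smoker and
#'   dead aggregates by age.
#' @export
autoplot.cess_trace <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(smoker = .data$S + .data$S_rel,
           former = rowSums(across(all_of(.f_states))),
           dead = .data$D) %>%
    select("age", "smoker", "former", "dead") %>%
    tidyr::pivot_longer(-"age", names_to = "state", values_to = "fraction") %>%
    mutate(state = factor(.data$state, c("dead", "former", "smoker")))
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$fraction,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age (years)", y = "Fraction of cohort",
                  fill = NULL,
                  title = paste0("Cohort trace: ", attr(object, "strategy"),
                                 " (", attr(object, "sex"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane
#'
#' @param object A `cess_psa`.
#' @param wtp Willingness-to-pay line to overlay (CAD/QALY); `NULL` for
#'   none.
#' @param ... Unused.
#' @return A ggplot scatter of the per-draw incremental cost against
#'   incremental QALYs.
#' @export
autoplot.cess_psa <- function(object, wtp = 50000, ...) {
  p <- ggplot2::ggplot(object$draws,
                       ggplot2::aes(.data$d_qaly, .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (CAD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(wtp))
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  p
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param psa A `cess_psa`.
#' @param grid Thresholds; defaults to the PSA's grid.
#' @return A ggplot of the probability cost-effective against the
#'   willingness-to-pay threshold.
#' @export
plot_ceac <- function(psa, grid = psa$settings$wtp_grid) {
  df <- ceac_curve(psa, grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda, .data$prob_ce)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (CAD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' @param tornado A `cess_tornado` tibble from [one_way_tornado()].
#' @param top Number of parameters to show (default all).
#' @return A ggplot: horizontal bars from the ICER at the lower bound to
#'   the ICER at the upper bound, widest swing on top, base-case ICER as
#'   a vertical line.
#' @export
plot_tornado <- function(tornado, top = nrow(tornado)) {
  base_icer <- attr(tornado, "base_icer")
  df <- as_tibble(unclass(tornado)) %>%
    filter(!is.na(.data$swing)) %>%
    dplyr::slice_head(n = top) %>%
    mutate(name = factor(.data$name, rev(.data$name)))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_lower,
                                       xend = .data$icer_at_upper,
                                       y = .data$name, yend = .data$name),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed") +
    ggplot2::labs(x = "ICER (CAD/QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}
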