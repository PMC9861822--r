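#' Plot a capacitance-voltage hysteresis loop
#'
#' Draws the two dynamic-capacitance branches against the command voltage:
#' the standard way of displaying the pinched loop.
#'
#' @param object A `memcap_curves` (from [capacitance_loops()] or
#'   [steady_current_vs_voltage()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.memcap_curves <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("U_V", "C_up_F", "C_down_F")],
    cols = c("C_up_F", "C_down_F"), names_to = "branch",
    values_to = "C_F")
  df$branch <- ifelse(df$branch == "C_up_F", "rising ramp",
                      "falling ramp (time-inverted)")
  ggplot2::ggplot(df, ggplot2::aes(x = 1e3 * .data$U_V, y = 1e12 * .data$C_F,
                                   colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "command voltage (mV)", y = "dynamic capacitance (pF)",
                  colour = NULL,
                  title = sprintf("capacitance-voltage loop (%s)",
                                  attr(object, "source") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a voltage-clamp trace
#'
#' @param object A `memcap_trace`.
#' @param periods How many leading drive periods to show (`Inf` for all).
#' @param ... Unused.
#' @return A ggplot object with current and command voltage panels.
#' @export
autoplot.memcap_trace <- function(object, periods = 5, ...) {
  drive <- attr(object, "drive")
  tbl <- tibble::as_tibble(object)
  if (is.finite(periods) && !is.null(drive))
    tbl <- tbl[tbl$time_s < periods * drive$T, ]
  df <- tibble::tibble(
    time_s = rep(tbl$time_s, 2),
    value = c(1e12 * tbl$current_A, 1e3 * tbl$voltage_V),
    what = rep(c("current (pA)", "command voltage (mV)"),
               each = nrow(tbl)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a folded paired-ramp response
#'
#' @param object A `memcap_fold`.
#' @param ... Unused.
#' @return A ggplot object showing both folded current branches versus
#'   voltage.
#' @export
autoplot.memcap_fold <- function(object, ...) {
  cv <- object$curves
  df <- tidyr::pivot_longer(cv[, c("U_V", "I_up_A", "I_down_inv_A")],
                            cols = c("I_up_A", "I_down_inv_A"),
                            names_to = "branch", values_to = "i_A")
  df$branch <- ifelse(df$branch == "I_up_A", "rising ramp",
                      "falling ramp (time-inverted)")
  ggplot2::ggplot(df, ggplot2::aes(x = 1e3 * .data$U_V, y = 1e12 * .data$i_A,
                                   colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "command voltage (mV)", y = "current (pA)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a membrane estimate against its data
#'
#' Shows the paired-ramp decomposition of the folded data (capacitance
#' curve `half_diff / k` and conductance curve `half_sum`) with the
#' closed-form curves at the recovered parameters overlaid.
#'
#' @param object A `memcap_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.memcap_fit <- function(object, ...) {
  d <- augment(object)
  k <- object$drive$k
  df <- tibble::tibble(
    U_mV = rep(1e3 * d$U_V, 2),
    value = c(1e12 * d$half_diff_A / k, 1e12 * d$half_sum_A),
    fitted = c(1e12 * (d$.fitted_I_up_A - d$.fitted_I_down_inv_A) / (2 * k),
               1e12 * (d$.fitted_I_up_A + d$.fitted_I_down_inv_A) / 2),
    panel = rep(c("capacitance: half-difference / k (pF)",
                  "conductance: half-sum (pA)"), each = nrow(d)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$U_mV)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.5,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "command voltage (mV)", y = NULL) +
    ggplot2::theme_minimal()
}
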