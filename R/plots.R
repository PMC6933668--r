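#' Plot a simulated trajectory
#'
#' Liquid-phase glucose and xylose concentrations (g/L) and the
#' insoluble-solids fraction against time; a dotted vertical line marks the
#' batch-to-continuous switch when present.
#'
#' @param object An `eh_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eh_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time_h", "c_g_g_per_L",
                  "c_x_g_per_L", "f_is"),
    cols = -"time_h", names_to = "series", values_to = "value"
  )
  labels <- c(c_g_g_per_L = "glucose (g/L)", c_x_g_per_L = "xylose (g/L)",
              f_is = "insoluble solids (-)")
  long$series <- labels[long$series]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h,
                                          y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = NULL)
  sw <- attr(object, "switch_h")
  if (!is.null(sw)) {
    p <- p + ggplot2::geom_vline(xintercept = sw, linetype = "dotted")
  }
  p
}

#' Plot a sensitivity sweep
#'
#' One panel per response, one line per parameter delta.
#'
#' @param object An `eh_sweep` from [run_sweep()].
#' @param response Response column to plot (`"X_t"`, `"c_g_g_per_L"` or
#'   `"f_is"`); defaults to conversion for batch sweeps and glucose for CEH.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eh_sweep <- function(object, response = NULL, ...) {
  if (is.null(response)) {
    response <- if (identical(attr(object, "scenario"), "ceh")) {
      "c_g_g_per_L"
    } else "X_t"
  }
  df <- dplyr::filter(tibble::as_tibble(object), .data$ok)
  df$delta_lab <- sprintf("%+.0f%%", 100 * df$delta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h,
                                   y = .data[[response]],
                                   color = .data$delta_lab)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = response, color = "delta",
                  title = unique(df$parameter))
}

#' Plot fitted curves against observations
#'
#' @param object An `eh_fit` from [fit_batch()].
#' @param ... Unused.
#' @return A ggplot object faceted by observable, colored by condition.
#' @export
autoplot.eh_fit <- function(object, ...) {
  r <- object$residuals
  ggplot2::ggplot(r, ggplot2::aes(x = .data$time_h,
                                  color = .data$condition_id)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL, color = "condition")
}
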