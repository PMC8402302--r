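#' Plot a generated stimulus or FHN trace
#'
#' @param object A `memsyn_ts` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.memsyn_ts <- function(object, ...) {
  ycol <- if ("x" %in% names(object)) "x" else "u"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time", y = ycol) +
    ggplot2::theme_minimal()
}

#' Plot I-V cycles coloured by loop segment
#'
#' @param object A `memsyn_iv` tibble from [iv_sweep()].
#' @param ... Unused.
#' @export
autoplot.memsyn_iv <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$v, y = .data$i,
                               colour = .data$segment,
                               group = .data$cycle)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = "voltage (V)", y = "current (model units)",
                  colour = "segment") +
    ggplot2::theme_minimal()
}

#' Plot a coupled trace: membrane potentials and device forcing
#'
#' @param object A `memsyn_trace` from [simulate_coupled()].
#' @param ... Unused.
#' @export
autoplot.memsyn_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("t", "u1", "u2", "c")],
    cols = c("u1", "u2", "c"), names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#2c7fb8") +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (model units)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a regime map from a coupling or amplitude sweep
#'
#' @param object A `memsyn_map` tibble.
#' @param ... Unused.
#' @export
autoplot.memsyn_map <- function(object, ...) {
  value_name <- attr(object, "value_name") %||% names(object)[1]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[value_name]], y = .data$regime,
                               colour = .data$ratio)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = value_name, y = "regime", colour = "ratio") +
    ggplot2::theme_minimal()
}

#' Phase-portrait plot of a coupled trace
#'
#' @param trace A `memsyn_trace`.
#' @param transient_discard Fraction of the run discarded (default 0.5).
#' @export
plot_phase_portrait <- function(trace, transient_discard = 0.5) {
  pp <- phase_portrait(trace, transient_discard)
  ggplot2::ggplot(pp, ggplot2::aes(x = .data$u1, y = .data$u2)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.2, colour = "#2c7fb8") +
    ggplot2::labs(x = "presynaptic u1", y = "postsynaptic u2") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||%
NULL
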