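#' Plot a simulation trace
#'
#' Synchrony `|Z|` and normalized coupling strength `k/kmu` over time, with
#' stimulation periods shaded.
#'
#' @param object An `erna_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot erna_sim
#' @export
autoplot.erna_sim <- function(object, ...) {
  params <- attr(object, "params")
  df <- tibble(
    time_s = rep(object$time_s, 2),
    value = c(object$abs_z, object$k / params$kmu),
    series = rep(c("|Z|", "k / kmu"), each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram
#'
#' Time-frequency heat map of the Welch power spectral density (log10 scale).
#'
#' @param object An `erna_spectrogram`.
#' @param max_hz Upper frequency limit for display (default 400 Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot erna_spectrogram
#' @export
autoplot.erna_spectrogram <- function(object, max_hz = 400, ...) {
  df <- tidy(object)
  df <- df[df$frequency_hz <= max_hz, ]
  floor_psd <- max(df$psd) * 1e-8
  df$log_psd <- log10(pmax(df$psd, floor_psd))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$frequency_hz,
                                   fill = .data$log_psd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 PSD") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot paradigm feature series
#'
#' Mean feature time courses per condition with SEM ribbons.
#'
#' @param object An `erna_paradigm`.
#' @param measure Which measure to plot (default all, facetted).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot erna_paradigm
#' @export
autoplot.erna_paradigm <- function(object, measure = NULL, ...) {
  df <- object$features
  if (!is.null(measure)) df <- df[df$measure %in% measure, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                        colour = .data$condition,
                                        fill = .data$condition))
  if (any(!is.na(df$sem))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$sem,
                   ymax = .data$value + .data$sem),
      alpha = 0.25, colour = NA)
  }
  p + ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time since stimulation onset (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted frequency decay against the target curve
#'
#' @param paradigm An `erna_paradigm` from [run_fit_protocol()].
#' @param curve The target curve (default [target_curve()]).
#' @return A ggplot object.
#' @export
plot_fit_vs_target <- function(paradigm, curve = target_curve()) {
  df <- paradigm$features
  df <- df[df$measure == "frequency_hz", ]
  df$target <- target_decay(df$time_s, curve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sem,
                                      ymax = .data$value + .data$sem),
                         fill = "darkgreen", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "darkgreen") +
    ggplot2::geom_line(ggplot2::aes(y = .data$target), colour = "black",
                       linetype = 2) +
    ggplot2::labs(x = "time since stimulation onset (s)",
                  y = "peak frequency (Hz)") +
    ggplot2::theme_minimal()
}
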