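#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_point geom_step
#'   scale_fill_viridis_c facet_wrap labs theme_minimal
NULL

#' Plot a Doppler spectrogram
#'
#' Velocity-time heat map of log power, the familiar spectral-Doppler
#' display.
#'
#' @param object A `doppler_spectrogram`.
#' @param dynamic_range_db Displayed dynamic range below the maximum, dB.
#' @param ... Unused.
#' @method autoplot doppler_spectrogram
#' @export
autoplot.doppler_spectrogram <- function(object, dynamic_range_db = 40, ...) {
  d <- tidy(object)
  d$db <- 10 * log10(d$power / max(d$power) + 1e-300)
  d$db <- pmax(d$db, -dynamic_range_db)
  ggplot(d, aes(x = .data$t, y = .data$velocity, fill = .data$db)) +
    geom_raster() +
    scale_fill_viridis_c(name = "dB") +
    labs(x = "time (s)", y = "velocity (cm/s, uncorrected)") +
    theme_minimal()
}

#' Plot a colour M-mode
#'
#' Depth-time map of mean velocity for one transducer.
#'
#' @param object A `color_mmode`.
#' @param transducer Which transducer to show. Default 1.
#' @param ... Unused.
#' @method autoplot color_mmode
#' @export
autoplot.color_mmode <- function(object, transducer = 1, ...) {
  d <- object[object$transducer == transducer, ]
  ggplot(d, aes(x = .data$t, y = .data$depth_mm, fill = .data$mean_velocity)) +
    geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "black", high = "red",
                                  name = "cm/s") +
    labs(x = "time (s)", y = "depth (mm)") +
    theme_minimal()
}

#' Plot scenario traces
#'
#' Stacked velocity and pressure panels with ECG events marked.
#'
#' @param object A `scenario_traces`.
#' @param ... Unused.
#' @method autoplot scenario_traces
#' @export
autoplot.scenario_traces <- function(object, ...) {
  d <- object$trace |>
    tidyr::pivot_longer(c("velocity_cm_s", "pressure_mmHg"),
                        names_to = "channel", values_to = "value")
  ggplot(d, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Plot a maximum-velocity envelope
#'
#' @param object A `doppler_envelope`.
#' @param ... Unused.
#' @method autoplot doppler_envelope
#' @export
autoplot.doppler_envelope <- function(object, ...) {
  ggplot(object, aes(x = .data$t, y = .data$v_max, colour = .data$quality)) +
    geom_line(aes(group = 1), linewidth = 0.3) +
    labs(x = "time (s)", y = "envelope velocity (cm/s)") +
    theme_minimal()
}

#' Per-animal TAV-vs-MAP panels with model predictions
#'
#' The study-level scatter of 1-Hz TAV/MAP readings, one panel per animal,
#' overlaid with the per-animal fitted curves.
#'
#' @param object An `lmm_fit`.
#' @param ... Unused.
#' @method autoplot lmm_fit
#' @export
autoplot.lmm_fit <- function(object, ...) {
  pred <- predict_per_animal(object)
  ggplot(object$data, aes(x = .data$map, y = .data$tav)) +
    geom_point(alpha = 0.2, size = 0.5, colour = "grey40") +
    geom_line(data = pred, aes(y = .data$tav_pred), linetype = "dashed") +
    facet_wrap(~animal) +
    labs(x = "MAP (mmHg)", y = "TAV (cm/s)") +
    theme_minimal()
}

#' Flow-state strip chart
#'
#' @param object A `flow_state_series`.
#' @param ... Unused.
#' @method autoplot flow_state_series
#' @export
autoplot.flow_state_series <- function(object, ...) {
  ggplot(object, aes(x = .data$t_start, y = .data$state)) +
    geom_step(group = 1) +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}
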