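# ggplot2 visualisations for the main result types.

#' Plot a Clausius-Mossotti (or population) spectrum
#'
#' Real and imaginary components against log frequency, faceted.
#'
#' @param spectrum Data frame with `frequency_hz`, `re`, `im`.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(spectrum), "frequency_hz", "re", "im"),
    c("re", "im"),
    names_to = "component", values_to = "value"
  )
  long$component <- factor(long$component, c("re", "im"),
                           c("Re f_CM", "Im f_CM"))
  ggplot2::ggplot(long, ggplot2::aes(.data$frequency_hz, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Clausius-Mossotti factor")
}

#' @rdname plot_spectrum
#' @param object,... Passed from the generic.
#' @method autoplot cm_spectrum
#' @export
autoplot.cm_spectrum <- function(object, ...) plot_spectrum(object)

#' @rdname plot_spectrum
#' @method autoplot population_spectrum
#' @export
autoplot.population_spectrum <- function(object, ...) plot_spectrum(object)

#' Observed spectrum with the fitted model overlaid
#'
#' @param object A `shell_fit`.
#' @param ... Unused.
#' @return A ggplot with observed points and fitted lines per component.
#' @method autoplot shell_fit
#' @export
autoplot.shell_fit <- function(object, ...) {
  obs <- dplyr::mutate(tibble::as_tibble(object$spectrum), kind = "observed")
  fit <- dplyr::mutate(predict(object), kind = "fitted")
  long <- tidyr::pivot_longer(
    dplyr::bind_rows(obs[c("frequency_hz", "re", "im", "kind")], fit),
    c("re", "im"),
    names_to = "component", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$frequency_hz, .data$value)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$kind == "observed"),
                        size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$kind == "fitted"),
                       colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Normalised spectrum",
                  title = "Double-shell model fit")
}

#' Feature-plane scatter plot
#'
#' HF phase against electrical diameter, coloured by class label (the
#' classified or true label column, if present).
#'
#' @param features Feature tibble with `electrical_diameter_um`,
#'   `phase_hf_rad` and optionally `.pred_class` or `true_label`.
#' @param colour Column to colour by (default `.pred_class` if present,
#'   else `true_label`).
#' @return A ggplot.
#' @export
plot_feature_plane <- function(features, colour = NULL) {
  if (is.null(colour)) {
    colour <- if (".pred_class" %in% names(features)) ".pred_class"
      else if ("true_label" %in% names(features)) "true_label" else NULL
  }
  p <- ggplot2::ggplot(features, ggplot2::aes(
    .data$electrical_diameter_um, .data$phase_hf_rad
  ))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 0.5, alpha = 0.4)
  } else {
    p <- p + ggplot2::geom_point(size = 0.5, alpha = 0.4)
  }
  p + ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Electrical diameter (um)", y = "Phase at 500 MHz (rad)")
}

#' Recovery-rate bar chart
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot with a reference line at 100%.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$class, .data$recovery_pct)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Recovery rate (%)")
}

#' Plot a simulated waveform with detections
#'
#' @param waveform Tibble from [simulate_waveform()].
#' @param detections Optional tibble from [detect_events()].
#' @return A ggplot.
#' @export
plot_waveform <- function(waveform, detections = NULL) {
  p <- ggplot2::ggplot(waveform, ggplot2::aes(.data$t_s, .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Signal (arb.)")
  if (!is.null(detections) && nrow(detections) > 0) {
    p <- p + ggplot2::geom_vline(
      data = detections, ggplot2::aes(xintercept = .data$t0_s),
      colour = "red", linetype = "dotted"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
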