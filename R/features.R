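# Per-event feature extraction: bead size calibration, electrical diameter,
# high-frequency phase, and limit-of-detection filtering.

#' Construct an event table
#'
#' Per-particle dual-frequency impedance records: in-phase and quadrature
#' signal at 1 MHz (sizing) and at 500 MHz (internal properties), arbitrary
#' current units. Acquisition metadata (flow rate, duration, medium
#' conductivity) is carried as attributes.
#'
#' @param events Data frame with columns `timestamp_s`, `re_1mhz`, `im_1mhz`,
#'   `re_500mhz`, `im_500mhz`, and optionally `velocity_m_s`, `true_label`.
#' @param flow_rate Sample flow rate in uL/min, > 0.
#' @param duration Acquisition duration in s, > 0.
#' @param medium_conductivity Medium conductivity in S/m.
#' @return A tibble of class `event_table`.
#' @export
event_table <- function(events, flow_rate = 30, duration,
                        medium_conductivity = 2.9) {
  required <- c("timestamp_s", "re_1mhz", "im_1mhz", "re_500mhz", "im_500mhz")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("event table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(flow_rate > 0, duration > 0)
  events <- tibble::as_tibble(events)
  if (!"velocity_m_s" %in% names(events)) events$velocity_m_s <- NA_real_
  if (!"true_label" %in% names(events)) events$true_label <- NA_character_
  out <- tibble::new_tibble(events, class = "event_table")
  attr(out, "flow_rate") <- flow_rate
  attr(out, "duration") <- duration
  attr(out, "medium_conductivity") <- medium_conductivity
  out
}

#' Sampled volume of an event table
#'
#' `flow_rate * duration / 60` in uL.
#'
#' @param t An [event_table()] (or explicit `flow_rate`/`duration`).
#' @param flow_rate,duration Override the table's attributes.
#' @return Volume in uL.
#' @export
sampled_volume <- function(t = NULL, flow_rate = attr(t, "flow_rate"),
                           duration = attr(t, "duration")) {
  stopifnot(is.numeric(flow_rate), is.numeric(duration), flow_rate > 0, duration > 0)
  flow_rate * duration / 60
}

#' Calibrate the size axis from bead events
#'
#' The median 1 MHz real signal over calibration-bead events defines one
#' bead-volume unit; the median bead HF phase defines the run-level phase
#' baseline used by [phase_hf()].
#'
#' @param bead_events Data frame of bead events (>= 10 rows) with columns
#'   `re_1mhz`, `re_500mhz`, `im_500mhz`.
#' @param bead_diameter Nominal bead diameter in um (default 2).
#' @return An object of class `size_calibration`: `bead_diameter`,
#'   `bead_median_signal`, `phase_baseline`.
#' @export
calibrate_size <- function(bead_events, bead_diameter = 2) {
  stopifnot(is.data.frame(bead_events), bead_diameter > 0)
  if (nrow(bead_events) < 10) {
    stop("size calibration needs at least 10 bead events, got ", nrow(bead_events),
         call. = FALSE)
  }
  structure(
    list(
      bead_diameter = bead_diameter,
      bead_median_signal = stats::median(bead_events$re_1mhz),
      phase_baseline = stats::median(atan2(bead_events$im_500mhz, bead_events$re_500mhz))
    ),
    class = "size_calibration"
  )
}

#' Electrical diameter of events
#'
#' Cube root of the 1 MHz real signal, scaled so that the bead median maps to
#' the nominal bead diameter:
#' `d = bead_diameter * (re_1mhz / bead_median_signal)^(1/3)`. Events with a
#' non-positive sizing signal yield `NA` (flagged invalid).
#'
#' @param re_1mhz Numeric vector of 1 MHz real signals (or an event table,
#'   from which the column is taken).
#' @param calibration A [calibrate_size()] result.
#' @return Electrical diameters in um.
#' @export
electrical_diameter <- function(re_1mhz, calibration) {
  stopifnot(inherits(calibration, "size_calibration"))
  if (is.data.frame(re_1mhz)) re_1mhz <- re_1mhz$re_1mhz
  d <- calibration$bead_diameter * (re_1mhz / calibration$bead_median_signal)^(1 / 3)
  d[!is.finite(d) | re_1mhz <= 0] <- NA_real_
  d
}

#' High-frequency impedance phase of events
#'
#' Four-quadrant angle of the 500 MHz signal minus the run-level baseline
#' (median calibration-bead phase), wrapped to (-pi, pi]. Events with a zero
#' HF vector yield `NA`.
#'
#' @param events Data frame with `re_500mhz`, `im_500mhz`.
#' @param calibration A [calibrate_size()] result (supplies the baseline);
#'   alternatively pass `baseline` directly.
#' @param baseline Baseline angle in radians, overriding the calibration.
#' @return Baseline-subtracted phases in radians.
#' @export
phase_hf <- function(events, calibration = NULL, baseline = NULL) {
  if (is.null(baseline)) {
    stopifnot(inherits(calibration, "size_calibration"))
    baseline <- calibration$phase_baseline
  }
  raw <- atan2(events$im_500mhz, events$re_500mhz)
  raw[events$re_500mhz == 0 & events$im_500mhz == 0] <- NA_real_
  ph <- raw - baseline
  # wrap into (-pi, pi]
  ph - 2 * pi * ceiling((ph - pi) / (2 * pi))
}

#' Extract the (electrical diameter, HF phase) feature plane
#'
#' Computes both features for every event, drops invalid events and events
#' below the electrical-diameter limit of detection (boundary inclusive:
#' events at exactly `lod` are kept), and preserves event order.
#'
#' @param t An [event_table()] (any data frame with the event columns).
#' @param calibration A [calibrate_size()] result.
#' @param lod Limit of detection in um (default 1.5); events with diameter
#'   < `lod` are discarded.
#' @return A tibble with columns `event` (row index into `t`),
#'   `electrical_diameter_um`, `phase_hf_rad`, `true_label`.
#' @export
extract_features <- function(t, calibration, lod = 1.5) {
  stopifnot(is.data.frame(t))
  if (nrow(t) == 0) {
    return(tibble::tibble(
      event = integer(), electrical_diameter_um = numeric(),
      phase_hf_rad = numeric(), true_label = character()
    ))
  }
  d <- electrical_diameter(t$re_1mhz, calibration)
  ph <- phase_hf(t, calibration)
  keep <- !is.na(d) & !is.na(ph) & d >= lod
  tibble::tibble(
    event = which(keep),
    electrical_diameter_um = d[keep],
    phase_hf_rad = ph[keep],
    true_label = if ("true_label" %in% names(t)) t$true_label[keep] else NA_character_
  )
}
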