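# Plain-text I/O: event-table CSV (with acquisition metadata in comment
# headers), spectrum CSV (frequency_hz, re, im), and JSON reports.

EVENT_COLS <- c("timestamp_s", "re_1mhz", "im_1mhz", "re_500mhz", "im_500mhz",
                "velocity_m_s", "true_label")

#' Write an event table to CSV
#'
#' Acquisition metadata (flow rate, duration, medium conductivity) is stored
#' in `#`-prefixed header lines so the file round-trips losslessly through
#' [read_event_csv()].
#'
#' @param t An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(t, path) {
  stopifnot(is.data.frame(t))
  header <- c(
    sprintf("# flow_rate_ul_min: %.17g", attr(t, "flow_rate")),
    sprintf("# duration_s: %.17g", attr(t, "duration")),
    sprintf("# medium_conductivity_s_m: %.17g", attr(t, "medium_conductivity"))
  )
  writeLines(c(header, paste(EVENT_COLS, collapse = ",")), path)
  out <- as.data.frame(t)[, EVENT_COLS]
  if (nrow(out) > 0) {
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path A file written by [write_event_csv()] (or any CSV with the
#'   event columns and the metadata comment header).
#' @return An [event_table()].
#' @export
read_event_csv <- function(path) {
  head_lines <- readLines(path, n = 10)
  meta_line <- function(key, default) {
    hit <- grep(paste0("^# ", key, ":"), head_lines, value = TRUE)
    if (length(hit) == 0) return(default)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", hit[1]))
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing_cols <- setdiff(setdiff(EVENT_COLS, c("velocity_m_s", "true_label")),
                          names(df))
  if (length(missing_cols) > 0) {
    stop("event CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(EVENT_COLS, names(df))
  num_cols <- setdiff(num_cols, "true_label")
  df[num_cols] <- lapply(df[num_cols], as.numeric)
  if ("true_label" %in% names(df)) df$true_label <- as.character(df$true_label)
  event_table(
    df,
    flow_rate = meta_line("flow_rate_ul_min", 30),
    duration = meta_line("duration_s", max(df$timestamp_s, 1)),
    medium_conductivity = meta_line("medium_conductivity_s_m", 2.9)
  )
}

#' Round-trip an event table through CSV
#'
#' Writes then re-reads the table; numeric fields survive to full double
#' precision.
#'
#' @param t An [event_table()].
#' @param path Optional file path (default: a temporary file).
#' @return The re-read [event_table()].
#' @export
roundtrip_io <- function(t, path = tempfile(fileext = ".csv")) {
  write_event_csv(t, path)
  read_event_csv(path)
}

#' Write / read a spectrum CSV
#'
#' Columns `frequency_hz`, `re`, `im`.
#'
#' @param spectrum Data frame with `frequency_hz`, `re`, `im`.
#' @param path File path.
#' @return `write_spectrum_csv`: `path` invisibly; `read_spectrum_csv`: a
#'   tibble.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(all(c("frequency_hz", "re", "im") %in% names(spectrum)))
  readr::write_csv(as.data.frame(spectrum)[, c("frequency_hz", "re", "im")], path)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "ddd")
}
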