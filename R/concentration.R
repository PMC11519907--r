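# Concentration estimation and recovery-rate evaluation.

#' Estimate per-class concentrations from event counts
#'
#' `concentration = count / (flow_rate * duration / 60)` particles/uL; no
#' coincidence correction is applied.
#'
#' @param counts Named numeric vector or table: class label -> event count.
#' @param flow_rate Flow rate in uL/min, > 0.
#' @param duration Acquisition duration in s, > 0.
#' @return A tibble of class `concentration_report` with columns `class`,
#'   `count`, `concentration_ul` and attribute `volume_ul`.
#' @examples
#' estimate_concentration(c(beads = 3600), flow_rate = 30, duration = 120)
#' @export
estimate_concentration <- function(counts, flow_rate = 30, duration) {
  stopifnot(is.numeric(flow_rate), is.numeric(duration))
  if (flow_rate <= 0 || duration <= 0) {
    stop("flow rate and duration must be positive", call. = FALSE)
  }
  counts <- c(table_to_named(counts))
  vol <- flow_rate * duration / 60
  out <- tibble::tibble(
    class = names(counts),
    count = unname(as.numeric(counts)),
    concentration_ul = unname(as.numeric(counts)) / vol
  )
  out <- tibble::new_tibble(out, class = "concentration_report")
  attr(out, "volume_ul") <- vol
  out
}

table_to_named <- function(x) {
  if (is.table(x)) {
    out <- as.numeric(x)
    names(out) <- names(x)
    out
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' Recovery rate of estimated against true concentrations
#'
#' `recovery = 100 * estimated / true` percent per class. Classes with zero
#' or missing truth are skipped with a warning; true classes absent from the
#' estimate are reported with zero recovery.
#'
#' @param estimated A [estimate_concentration()] report.
#' @param truth Named numeric vector: class label -> true concentration
#'   (particles/uL), > 0.
#' @return A tibble of class `recovery_report` with columns `class`,
#'   `estimated_ul`, `true_ul`, `recovery_pct`.
#' @export
recovery_report <- function(estimated, truth) {
  stopifnot(is.data.frame(estimated),
            all(c("class", "concentration_ul") %in% names(estimated)),
            is.numeric(truth), !is.null(names(truth)))
  bad <- names(truth)[!is.finite(truth) | truth <= 0]
  if (length(bad) > 0) {
    warning("skipping class(es) with non-positive truth: ",
            paste(bad, collapse = ", "), call. = FALSE)
    truth <- truth[setdiff(names(truth), bad)]
  }
  est <- stats::setNames(estimated$concentration_ul, estimated$class)
  out <- tibble::tibble(
    class = names(truth),
    estimated_ul = unname(ifelse(is.na(est[names(truth)]), 0, est[names(truth)])),
    true_ul = unname(truth)
  )
  out$recovery_pct <- 100 * out$estimated_ul / out$true_ul
  tibble::new_tibble(out, class = "recovery_report")
}
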