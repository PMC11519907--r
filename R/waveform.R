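# Simplified multipeak waveform simulation and matched-filter event
# detection. A particle transiting the array of facing electrode pairs
# produces one Gaussian-shaped lobe per pair with alternating polarity; the
# lobe spacing in time encodes the particle velocity, the lobe height its
# impedance signal.

#' Electrode-array waveform template
#'
#' @param n_electrode_pairs Number of electrode pairs (default 9).
#' @param pitch Centre-to-centre electrode-pair spacing in metres.
#' @param sample_rate Acquisition sample rate in Hz (default 230 kHz).
#' @param lobe_width Gaussian lobe SD in seconds.
#' @param polarity Lobe polarity per pair (default alternating +1/-1).
#' @return An object of class `waveform_template`.
#' @export
waveform_template <- function(n_electrode_pairs = 9, pitch = 60e-6,
                              sample_rate = 230e3, lobe_width = 2.5e-5,
                              polarity = rep_len(c(1, -1), n_electrode_pairs)) {
  stopifnot(n_electrode_pairs >= 2, pitch > 0, sample_rate > 0, lobe_width > 0,
            length(polarity) == n_electrode_pairs)
  structure(
    list(n_electrode_pairs = n_electrode_pairs, pitch = pitch,
         sample_rate = sample_rate, lobe_width = lobe_width,
         polarity = polarity),
    class = "waveform_template"
  )
}

# Noise-free unit-amplitude transit waveform evaluated at times t (s) for a
# particle crossing the array centre at time t0 with the given velocity.
template_pulse <- function(t, template, velocity, t0 = 0) {
  centers <- (seq_len(template$n_electrode_pairs) -
                (template$n_electrode_pairs + 1) / 2) * template$pitch / velocity
  out <- numeric(length(t))
  for (j in seq_len(template$n_electrode_pairs)) {
    out <- out + template$polarity[j] *
      exp(-((t - t0 - centers[j])^2) / (2 * template$lobe_width^2))
  }
  out
}

#' Simulate a multipeak transit waveform
#'
#' Sum of alternating-polarity Gaussian lobes centred at the electrode-pair
#' positions divided by the particle velocity, scaled by the event
#' amplitude, plus white Gaussian noise, sampled at the template's rate.
#' Vector `amplitude`/`velocity`/`t0` arguments superpose several events in
#' one record.
#'
#' @param amplitude Event amplitude(s), arbitrary units.
#' @param velocity Particle velocity(ies) in m/s, > 0.
#' @param template A [waveform_template()].
#' @param noise_sd White-noise SD in the same units as `amplitude`.
#' @param duration Record length in s (default: transits plus a margin).
#' @param t0 Transit centre time(s) in s (default: centred).
#' @param seed Integer seed for the noise.
#' @return Tibble with columns `t_s`, `signal`.
#' @export
simulate_waveform <- function(amplitude, velocity, template = waveform_template(),
                              noise_sd = 0, duration = NULL, t0 = NULL,
                              seed = 1) {
  stopifnot(length(amplitude) == length(velocity))
  if (any(velocity <= 0)) stop("velocity must be positive", call. = FALSE)
  transit <- template$n_electrode_pairs * template$pitch / min(velocity)
  if (is.null(duration)) duration <- 3 * transit
  if (is.null(t0)) t0 <- duration / 2 + (seq_along(amplitude) - 1) * 3 * transit
  stopifnot(length(t0) == length(amplitude))
  t <- seq(0, duration, by = 1 / template$sample_rate)
  sig <- numeric(length(t))
  for (e in seq_along(amplitude)) {
    sig <- sig + amplitude[e] * template_pulse(t, template, velocity[e], t0[e])
  }
  if (noise_sd > 0) {
    withr::with_seed(seed, sig <- sig + stats::rnorm(length(t), 0, noise_sd))
  }
  tibble::tibble(t_s = t, signal = sig)
}

# Best-lag correlation of a sampled record with the unit template at a given
# velocity, restricted to lags in [lo, hi] (sample indices of the transit
# centre). Returns list(lag, score = sum(s*T), norm2 = sum(T^2)).
best_lag_fit <- function(signal, t, template, velocity, lo, hi) {
  half_n <- ceiling((template$n_electrode_pairs * template$pitch / velocity / 2 +
                       4 * template$lobe_width) * template$sample_rate)
  tt <- (-half_n:half_n) / template$sample_rate
  tp <- template_pulse(tt, template, velocity)
  norm2 <- sum(tp^2)
  best <- list(lag = NA_integer_, score = -Inf, norm2 = norm2)
  for (ctr in lo:hi) {
    i0 <- ctr - half_n; i1 <- ctr + half_n
    if (i0 < 1 || i1 > length(signal)) next
    sc <- sum(signal[i0:i1] * tp)
    if (sc > best$score) best <- list(lag = ctr, score = sc, norm2 = norm2)
  }
  best
}

#' Detect transit events by matched filtering
#'
#' Correlates the record with the unit template over a grid of candidate
#' velocities, flags correlation peaks above `threshold` noise standard
#' deviations (with non-maximum suppression over one transit time), then
#' refines each detection's velocity by golden-section search on the
#' correlation and estimates its amplitude by least squares against the
#' refined template. The velocity estimate corresponds to
#' `pitch / lobe spacing`.
#'
#' @param waveform Tibble from [simulate_waveform()] (columns `t_s`,
#'   `signal`) or a numeric signal vector.
#' @param template The [waveform_template()] used for matching.
#' @param velocity_range Candidate velocity span in m/s.
#' @param n_velocities Coarse velocity-grid size.
#' @param threshold Detection threshold in units of the matched-filter noise
#'   SD.
#' @param noise_sd Noise SD; estimated from the record (MAD) when `NULL`.
#' @return Tibble with one row per detection: `t0_s`, `amplitude`,
#'   `velocity_m_s`, `snr`. Zero rows when nothing exceeds the threshold.
#' @export
detect_events <- function(waveform, template = waveform_template(),
                          velocity_range = c(0.4, 1.6), n_velocities = 25,
                          threshold = 5, noise_sd = NULL) {
  if (is.data.frame(waveform)) {
    signal <- waveform$signal
  } else {
    signal <- as.numeric(waveform)
  }
  n <- length(signal)
  if (is.null(noise_sd)) noise_sd <- stats::mad(signal)
  if (noise_sd <= 0) noise_sd <- stats::sd(signal)
  if (!is.finite(noise_sd) || noise_sd <= 0) noise_sd <- 1e-12
  vgrid <- exp(seq(log(velocity_range[1]), log(velocity_range[2]),
                   length.out = n_velocities))
  # coarse matched-filter statistic: max over velocities at each lag
  stat <- rep(-Inf, n)
  vbest <- rep(NA_real_, n)
  for (v in vgrid) {
    half_n <- ceiling((template$n_electrode_pairs * template$pitch / v / 2 +
                         4 * template$lobe_width) * template$sample_rate)
    tt <- (-half_n:half_n) / template$sample_rate
    tp <- template_pulse(tt, template, v)
    corr <- stats::filter(signal, rev(tp), method = "convolution", sides = 2)
    z <- as.numeric(corr) / (noise_sd * sqrt(sum(tp^2)))
    z[is.na(z)] <- -Inf
    upd <- z > stat
    stat[upd] <- z[upd]
    vbest[upd] <- v
  }
  # peaks above threshold with non-max suppression over one transit time
  suppress <- ceiling(template$n_electrode_pairs * template$pitch /
                        min(vgrid) * template$sample_rate)
  cand <- which(stat >= threshold)
  cand <- cand[order(stat[cand], decreasing = TRUE)]
  centers <- integer(0)
  for (i in cand) {
    if (all(abs(centers - i) > suppress)) centers <- c(centers, i)
  }
  if (length(centers) == 0) {
    return(tibble::tibble(t0_s = numeric(), amplitude = numeric(),
                          velocity_m_s = numeric(), snr = numeric()))
  }
  centers <- sort(centers)
  dt <- 1 / template$sample_rate
  out <- purrr::map_dfr(centers, function(ctr) {
    v0 <- vbest[ctr]
    win <- ceiling(template$lobe_width * template$sample_rate) + 2
    score_at <- function(v) {
      best_lag_fit(signal, NULL, template, v, max(1, ctr - win), ctr + win)$score
    }
    opt <- stats::optimize(score_at, lower = v0 / 1.25, upper = v0 * 1.25,
                           maximum = TRUE, tol = v0 * 1e-4)
    fit <- best_lag_fit(signal, NULL, template, opt$maximum,
                        max(1, ctr - win), ctr + win)
    tibble::tibble(
      t0_s = (fit$lag - 1) * dt,
      amplitude = fit$score / fit$norm2,
      velocity_m_s = opt$maximum,
      snr = stat[ctr]
    )
  })
  out
}
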