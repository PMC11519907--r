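# Seeded synthetic-data generators emulating the dual-frequency impedance
# cytometer: lognormal size distributions, class-dependent HF phase offsets
# with 1/volume phase noise, calibration-bead spike-ins, coliving-bacteria
# contamination, equal-volumetric mixtures, and noisy population spectra.

#' Specify a synthetic particle class
#'
#' Event-level generative model for one particle class: diameters are
#' lognormal (median `size_median`, geometric SD `size_gsd`), optionally a
#' mixture of subpopulations sharing the GSD; the 500 MHz phase is the class
#' offset plus Gaussian noise whose SD grows as the diameter shrinks
#' (`phase_noise_coeff / d^3`, the 1/volume law that reproduces the broadening
#' of phase distributions toward small diameters); the 1 MHz real signal is
#' proportional to particle volume with multiplicative measurement noise.
#'
#' @param label Class label.
#' @param size_median Median diameter in um, > 0.
#' @param size_gsd Geometric standard deviation, >= 1.
#' @param phase_offset Mean HF phase in radians (before baseline removal).
#' @param phase_noise_coeff Phase noise coefficient in rad*um^3
#'   (sd = coeff / diameter^3).
#' @param amp_noise_cv Coefficient of variation of the multiplicative signal
#'   noise.
#' @param contamination_fraction Expected coliving-contaminant events as a
#'   fraction of class events, in \[0, 1).
#' @param contamination_spec Nested `class_gen_spec` for the contaminant
#'   (required when `contamination_fraction > 0`).
#' @param subpop_medians,subpop_weights Optional subpopulation medians (um)
#'   and mixture weights for multimodal classes (e.g. a 2/3/5/8 um
#'   microplastic mix); weights are normalised to sum to 1.
#' @return An object of class `class_gen_spec`.
#' @export
class_gen_spec <- function(label, size_median, size_gsd = 1.2,
                           phase_offset = 0, phase_noise_coeff = 0.4,
                           amp_noise_cv = 0.05,
                           contamination_fraction = 0,
                           contamination_spec = NULL,
                           subpop_medians = NULL, subpop_weights = NULL) {
  stopifnot(
    is.character(label), length(label) == 1,
    size_median > 0, size_gsd >= 1, phase_noise_coeff >= 0, amp_noise_cv >= 0,
    contamination_fraction >= 0, contamination_fraction < 1
  )
  if (contamination_fraction > 0 && !inherits(contamination_spec, "class_gen_spec")) {
    stop("contamination_fraction > 0 requires a contamination_spec", call. = FALSE)
  }
  if (!is.null(subpop_medians)) {
    if (is.null(subpop_weights)) subpop_weights <- rep(1, length(subpop_medians))
    stopifnot(length(subpop_weights) == length(subpop_medians),
              all(subpop_medians > 0), all(subpop_weights > 0))
    subpop_weights <- subpop_weights / sum(subpop_weights)
  }
  structure(
    list(
      label = label, size_median = size_median, size_gsd = size_gsd,
      phase_offset = phase_offset, phase_noise_coeff = phase_noise_coeff,
      amp_noise_cv = amp_noise_cv,
      contamination_fraction = contamination_fraction,
      contamination_spec = contamination_spec,
      subpop_medians = subpop_medians, subpop_weights = subpop_weights
    ),
    class = "class_gen_spec"
  )
}

#' Default coliving-bacteria contaminant specification
#'
#' Small membranous background particles present in non-axenic phytoplankton
#' cultures; median 1.3 um, mostly at or below the detection limit.
#'
#' @return A [class_gen_spec()].
#' @export
bacteria_spec <- function() {
  class_gen_spec("bacteria", size_median = 1.3, size_gsd = 1.2,
                 phase_offset = 0.16)
}

#' Default synthetic class specifications
#'
#' Five particle classes emulating the mixture experiment: a multimodal
#' microplastic mix (2/3/5/8 um solid beads, high HF phase), three larger
#' phytoplankton monocultures, and one smallest phytoplankton whose size
#' distribution is partially below the 1.5 um detection limit. Phytoplankton
#' cultures carry 10% coliving-bacteria contamination. Solid plastics sit at
#' a high HF phase offset; membranous cells cluster at low offsets.
#'
#' @param contamination Contamination fraction for the phytoplankton classes
#'   (default 0.1; set 0 to disable).
#' @return Named list of [class_gen_spec()]s: `microplastic`, `i_galbana`,
#'   `c_vulgaris`, `p_purpureum`, `synechococcus`.
#' @export
default_class_specs <- function(contamination = 0.1) {
  bact <- if (contamination > 0) bacteria_spec() else NULL
  list(
    microplastic = class_gen_spec(
      "microplastic", size_median = 3, size_gsd = 1.05, phase_offset = 0.30,
      subpop_medians = c(2, 3, 5, 8)
    ),
    i_galbana = class_gen_spec(
      "i_galbana", size_median = 5, size_gsd = 1.2, phase_offset = 0.10,
      contamination_fraction = contamination, contamination_spec = bact
    ),
    c_vulgaris = class_gen_spec(
      "c_vulgaris", size_median = 3.5, size_gsd = 1.2, phase_offset = 0.12,
      contamination_fraction = contamination, contamination_spec = bact
    ),
    p_purpureum = class_gen_spec(
      "p_purpureum", size_median = 6, size_gsd = 1.2, phase_offset = 0.08,
      contamination_fraction = contamination, contamination_spec = bact
    ),
    synechococcus = class_gen_spec(
      "synechococcus", size_median = 1.2, size_gsd = 1.2, phase_offset = 0.14,
      contamination_fraction = contamination, contamination_spec = bact
    )
  )
}

#' Calibration-bead specification
#'
#' Monodisperse 2 um polystyrene spike-in beads.
#'
#' @return A [class_gen_spec()] labelled `"bead"`.
#' @export
bead_spec <- function() {
  class_gen_spec("bead", size_median = 2, size_gsd = 1.05, phase_offset = 0.30)
}

# Draw n events from a class spec; assumes the RNG state is managed by the
# caller. Signals are in bead-volume units: a nominal 2 um particle has
# expected re_1mhz = 1.
draw_class_events <- function(spec, n, duration) {
  if (n == 0) {
    return(tibble::tibble(
      timestamp_s = numeric(), re_1mhz = numeric(), im_1mhz = numeric(),
      re_500mhz = numeric(), im_500mhz = numeric(),
      velocity_m_s = numeric(), true_label = character()
    ))
  }
  if (is.null(spec$subpop_medians)) {
    medians <- rep(spec$size_median, n)
  } else {
    medians <- sample(spec$subpop_medians, n, replace = TRUE,
                      prob = spec$subpop_weights)
  }
  d <- medians * exp(stats::rnorm(n, 0, log(spec$size_gsd)))
  re_lf <- (d / 2)^3 * exp(stats::rnorm(n, 0, spec$amp_noise_cv))
  im_lf <- re_lf * tan(stats::rnorm(n, 0, 0.01))
  phase <- spec$phase_offset + stats::rnorm(n, 0, spec$phase_noise_coeff / d^3)
  amp_hf <- re_lf * exp(stats::rnorm(n, 0, spec$amp_noise_cv))
  tibble::tibble(
    timestamp_s = stats::runif(n, 0, duration),
    re_1mhz = re_lf, im_1mhz = im_lf,
    re_500mhz = amp_hf * cos(phase), im_500mhz = amp_hf * sin(phase),
    velocity_m_s = stats::rnorm(n, 0.8, 0.05),
    true_label = rep(spec$label, n)
  )
}

# Draw a Poisson event count and the events for a spec plus its contaminant.
draw_component <- function(spec, concentration, volume, duration) {
  n <- stats::rpois(1, concentration * volume)
  ev <- draw_class_events(spec, n, duration)
  if (spec$contamination_fraction > 0) {
    nc <- stats::rpois(1, spec$contamination_fraction * concentration * volume)
    ev <- dplyr::bind_rows(ev, draw_class_events(spec$contamination_spec, nc, duration))
  }
  ev
}

#' Generate a monodisperse (single-class) acquisition
#'
#' Simulates recording one monoculture or monodisperse plastic sample with
#' calibration-bead spike-ins: Poisson event counts at the requested
#' concentrations, lognormal diameters, volume-proportional 1 MHz signals,
#' class phase offsets with 1/d^3 phase noise, contaminant events when the
#' spec requests them, and uniform (Poisson-process) timestamps. Fully
#' reproducible for a given seed.
#'
#' @param spec A [class_gen_spec()].
#' @param concentration Class concentration in particles/uL.
#' @param bead_concentration Bead spike-in concentration in particles/uL
#'   (default 100).
#' @param flow_rate Flow rate in uL/min (default 30).
#' @param duration Acquisition duration in s.
#' @param seed Integer seed.
#' @param beads Bead [class_gen_spec()] (default [bead_spec()]).
#' @return An [event_table()] ordered by timestamp, with attribute
#'   `truth`: named vector of realised concentrations (count/volume) per
#'   label.
#' @export
gen_monoculture <- function(spec, concentration, bead_concentration = 100,
                            flow_rate = 30, duration = 60, seed = 1,
                            beads = bead_spec()) {
  stopifnot(inherits(spec, "class_gen_spec"), concentration >= 0,
            bead_concentration >= 0, duration > 0)
  vol <- flow_rate * duration / 60
  withr::with_seed(seed, {
    ev <- dplyr::bind_rows(
      draw_component(spec, concentration, vol, duration),
      draw_class_events(beads, stats::rpois(1, bead_concentration * vol), duration)
    )
  })
  ev <- dplyr::arrange(ev, .data$timestamp_s)
  out <- event_table(ev, flow_rate = flow_rate, duration = duration)
  attr(out, "truth") <- realized_truth(ev, vol)
  out
}

realized_truth <- function(events, volume) {
  counts <- table(events$true_label)
  stats::setNames(as.numeric(counts) / volume, names(counts))
}

#' Generate an equal-volumetric mixture acquisition
#'
#' Mixes several stocks at given volumetric fractions: each component's
#' effective concentration is its stock concentration times its fraction
#' (five equal stocks contribute stock/5 each). Contaminants travel with
#' their host components; calibration beads are spiked at
#' `bead_concentration`. Events are interleaved by timestamp.
#'
#' @param stocks Named numeric vector: component label -> stock
#'   concentration (particles/uL).
#' @param class_specs Named list of [class_gen_spec()]s covering every stock
#'   label.
#' @param volumetric_ratio Per-component fractions summing to 1 (default
#'   equal).
#' @param bead_concentration Bead spike-in concentration (default 200).
#' @param flow_rate,duration,seed,beads As in [gen_monoculture()].
#' @return An [event_table()] with attribute `truth` (realised
#'   concentrations per label, contaminants under their own label) and
#'   attribute `nominal_truth` (the diluted stock concentrations).
#' @export
gen_mixture <- function(stocks, class_specs,
                        volumetric_ratio = rep(1 / length(stocks), length(stocks)),
                        bead_concentration = 200,
                        flow_rate = 30, duration = 60, seed = 1,
                        beads = bead_spec()) {
  stopifnot(is.numeric(stocks), !is.null(names(stocks)), all(stocks >= 0),
            length(volumetric_ratio) == length(stocks))
  if (abs(sum(volumetric_ratio) - 1) > 1e-9) {
    stop("volumetric fractions must sum to 1", call. = FALSE)
  }
  missing_specs <- setdiff(names(stocks), names(class_specs))
  if (length(missing_specs) > 0) {
    stop("no class spec for component(s): ", paste(missing_specs, collapse = ", "),
         call. = FALSE)
  }
  vol <- flow_rate * duration / 60
  effective <- stocks * volumetric_ratio
  withr::with_seed(seed, {
    parts <- purrr::map(names(stocks), function(lbl) {
      draw_component(class_specs[[lbl]], effective[[lbl]], vol, duration)
    })
    parts <- c(parts, list(
      draw_class_events(beads, stats::rpois(1, bead_concentration * vol), duration)
    ))
  })
  ev <- dplyr::arrange(dplyr::bind_rows(parts), .data$timestamp_s)
  out <- event_table(ev, flow_rate = flow_rate, duration = duration)
  attr(out, "truth") <- realized_truth(ev, vol)
  attr(out, "nominal_truth") <- c(effective, bead = bead_concentration)
  out
}

#' Generate a noisy population-averaged spectrum
#'
#' Emulates averaging the differential current over `n_cells` cells at each
#' excitation frequency: the observed value is the particle's CM factor
#' times `scale`, perturbed by complex Gaussian noise of standard deviation
#' `noise_sd / sqrt(n_cells)` per component (relative).
#'
#' @param particle A [shelled_particle()] or [homogeneous_particle()].
#' @param medium The suspending [material()].
#' @param frequencies Frequencies in Hz.
#' @param n_cells Number of cells averaged (default 10000).
#' @param noise_sd Relative per-cell noise SD (>= 0).
#' @param scale Multiplicative scale (cell/bead volume ratio left by bead
#'   normalisation).
#' @param seed Integer seed.
#' @return List with `spectrum` (a [population_spectrum()]) and `truth`
#'   (list: `particle`, `medium`, `scale`, `noise_sd`, `n_cells`).
#' @export
gen_population_spectrum <- function(particle, medium = seawater_medium(),
                                    frequencies = log_frequency_grid(),
                                    n_cells = 10000, noise_sd = 0, scale = 1,
                                    seed = 1) {
  stopifnot(n_cells >= 1)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  s <- cm_spectrum(particle, medium, frequencies)
  fcm <- complex(real = s$re, imaginary = s$im)
  withr::with_seed(seed, {
    noise <- complex(
      real = stats::rnorm(length(fcm), 0, noise_sd / sqrt(n_cells)),
      imaginary = stats::rnorm(length(fcm), 0, noise_sd / sqrt(n_cells))
    )
  })
  obs <- scale * fcm * (1 + noise)
  list(
    spectrum = population_spectrum(frequencies, obs, n_cells = n_cells),
    truth = list(particle = particle, medium = medium, scale = scale,
                 noise_sd = noise_sd, n_cells = n_cells)
  )
}
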