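# Forward dielectric model: complex permittivities, Maxwell-Garnett mixing,
# concentric-shell collapse, Clausius-Mossotti spectra, relaxation extraction.
# Sign convention throughout: time factor e^{+j omega t}, so a lossy material
# has complex permittivity eps* = eps_r*eps0 - j*sigma/omega (F/m, absolute).

#' Vacuum permittivity (F/m)
#' @keywords internal
EPS0 <- 8.854e-12

#' Define a dielectric material
#'
#' A material is a (relative permittivity, conductivity) pair describing any
#' homogeneous phase of the model: cytoplasm, lipid, cell membrane, scale
#' layer, plastic, or the suspending medium.
#'
#' @param relative_permittivity Dimensionless relative permittivity, >= 1.
#' @param conductivity Conductivity in S/m, >= 0.
#' @return An object of class `dielectric_material`.
#' @examples
#' seawater <- material(78, 2.9)
#' polystyrene <- material(2.55, 0)
#' @export
material <- function(relative_permittivity, conductivity) {
  stopifnot(
    is.numeric(relative_permittivity), length(relative_permittivity) == 1,
    is.finite(relative_permittivity), relative_permittivity >= 1,
    is.numeric(conductivity), length(conductivity) == 1,
    is.finite(conductivity), conductivity >= 0
  )
  structure(
    list(relative_permittivity = relative_permittivity, conductivity = conductivity),
    class = "dielectric_material"
  )
}

#' @export
print.dielectric_material <- function(x, ...) {
  cat(sprintf(
    "<dielectric_material> eps_r = %g, sigma = %g S/m\n",
    x$relative_permittivity, x$conductivity
  ))
  invisible(x)
}

#' Complex absolute permittivity of a material
#'
#' Returns `eps_r * eps0 - 1i * sigma / (2 pi f)` (F/m) under the e^{+j omega t}
#' convention, vectorised over frequency.
#'
#' @param m A [material()].
#' @param f Frequencies in Hz, all > 0.
#' @return Complex vector, one value per frequency.
#' @export
complex_permittivity <- function(m, f) {
  stopifnot(inherits(m, "dielectric_material"), is.numeric(f), length(f) >= 1)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("frequencies must be finite and positive", call. = FALSE)
  }
  complex(
    real = rep(m$relative_permittivity * EPS0, length(f)),
    imaginary = -m$conductivity / (2 * pi * f)
  )
}

#' Clausius-Mossotti factor
#'
#' The complex polarizability contrast `(eps_p - eps_m) / (eps_p + 2 eps_m)`
#' between a spherical particle and its suspending medium. For passive
#' materials its real part lies in \[-0.5, 1\].
#'
#' @param eps_p Complex particle permittivity (or vector over frequency).
#' @param eps_m Complex medium permittivity (same length or length 1).
#' @return Complex vector of CM factors.
#' @export
clausius_mossotti <- function(eps_p, eps_m) {
  denom <- eps_p + 2 * eps_m
  if (any(abs(denom) == 0)) {
    stop("degenerate Clausius-Mossotti denominator: eps_p + 2*eps_m = 0", call. = FALSE)
  }
  (eps_p - eps_m) / denom
}

#' Maxwell-Garnett effective-medium mixture
#'
#' Effective permittivity of a host containing a volume fraction `phi` of
#' dilute spherical inclusions:
#' `eps_mix = host * (1 + 2 phi F) / (1 - phi F)` with
#' `F = (inclusion - host) / (inclusion + 2 host)`. Used for lipid vesicles
#' suspended in cytoplasm.
#'
#' @param host,inclusion Complex permittivities (vectors over frequency).
#' @param phi Inclusion volume fraction in \[0, 1\].
#' @return Complex effective permittivity.
#' @export
mg_mixture <- function(host, inclusion, phi) {
  stopifnot(is.numeric(phi), length(phi) == 1, is.finite(phi))
  if (phi < 0 || phi > 1) {
    stop("inclusion volume fraction must lie in [0, 1]", call. = FALSE)
  }
  FF <- (inclusion - host) / (inclusion + 2 * host)
  host * (1 + 2 * phi * FF) / (1 - phi * FF)
}

#' Collapse one concentric shell onto a core
#'
#' Equivalent homogeneous permittivity of a sphere of radius `r_out` made of a
#' core (radius `r_in`, permittivity `inner`) surrounded by a shell of
#' permittivity `shell`:
#' `eps_eq = shell * (g^3 + 2 G) / (g^3 - G)`, `g = r_out / r_in`,
#' `G = (inner - shell) / (inner + 2 shell)`.
#'
#' @param inner,shell Complex permittivities (vectors over frequency).
#' @param r_in,r_out Core and outer radii in metres, `0 < r_in < r_out`.
#' @return Complex equivalent permittivity.
#' @export
shell_collapse <- function(inner, shell, r_in, r_out) {
  stopifnot(is.numeric(r_in), is.numeric(r_out), length(r_in) == 1, length(r_out) == 1)
  if (!(r_in > 0 && r_out > r_in)) {
    stop("shell radii must satisfy 0 < r_in < r_out", call. = FALSE)
  }
  g3 <- (r_out / r_in)^3
  G <- (inner - shell) / (inner + 2 * shell)
  shell * (g3 + 2 * G) / (g3 - G)
}

#' Construct a shell layer
#'
#' @param material The shell [material()].
#' @param thickness Shell thickness in metres, > 0.
#' @return An object of class `shell_layer`.
#' @export
shell_layer <- function(material, thickness) {
  stopifnot(
    inherits(material, "dielectric_material"),
    is.numeric(thickness), length(thickness) == 1,
    is.finite(thickness), thickness > 0
  )
  structure(list(material = material, thickness = thickness), class = "shell_layer")
}

#' Construct a multishell particle
#'
#' A sphere whose inner core is a Maxwell-Garnett mixture of a host phase
#' (cytoplasm) and lipid inclusions, wrapped in an ordered series of
#' concentric shells (innermost first; typically the plasma membrane then an
#' outer scale layer).
#'
#' @param outer_radius Outer radius in metres, > total shell thickness.
#' @param core_host Core host [material()] (cytoplasm).
#' @param lipid Lipid inclusion [material()].
#' @param lipid_fraction Lipid volume fraction of the core, in \[0, 1).
#' @param shells List of [shell_layer()]s, innermost first.
#' @param core_premixed If `TRUE`, `core_host` is taken as the already-mixed
#'   core permittivity and `lipid`/`lipid_fraction` are ignored (the
#'   alternative reading of reported core values as post-mixture values).
#' @return An object of class `shelled_particle`.
#' @export
shelled_particle <- function(outer_radius, core_host, lipid,
                             lipid_fraction = 0, shells = list(),
                             core_premixed = FALSE) {
  stopifnot(
    is.numeric(outer_radius), length(outer_radius) == 1, outer_radius > 0,
    inherits(core_host, "dielectric_material"),
    inherits(lipid, "dielectric_material"),
    is.numeric(lipid_fraction), lipid_fraction >= 0, lipid_fraction < 1,
    is.list(shells), all(vapply(shells, inherits, logical(1), "shell_layer"))
  )
  total_shell <- sum(vapply(shells, function(s) s$thickness, numeric(1)))
  if (total_shell >= outer_radius) {
    stop("total shell thickness must be smaller than the outer radius", call. = FALSE)
  }
  structure(
    list(
      outer_radius = outer_radius, core_host = core_host, lipid = lipid,
      lipid_fraction = lipid_fraction, shells = shells,
      core_premixed = isTRUE(core_premixed)
    ),
    class = "shelled_particle"
  )
}

#' Construct a homogeneous particle
#'
#' A solid dielectric sphere such as a polystyrene or PMMA calibration bead.
#'
#' @param radius Radius in metres, > 0.
#' @param material The particle [material()].
#' @return An object of class `homogeneous_particle`.
#' @export
homogeneous_particle <- function(radius, material) {
  stopifnot(
    is.numeric(radius), length(radius) == 1, is.finite(radius), radius > 0,
    inherits(material, "dielectric_material")
  )
  structure(list(radius = radius, material = material), class = "homogeneous_particle")
}

#' Effective complex permittivity of a particle
#'
#' For a [shelled_particle()]: the lipid inclusions are mixed into the core
#' host by [mg_mixture()], then each shell is collapsed onto the growing core
#' innermost-first by [shell_collapse()]. For a [homogeneous_particle()]: the
#' material's [complex_permittivity()].
#'
#' @param p A particle.
#' @param f Frequencies in Hz.
#' @return Complex vector of equivalent permittivities, one per frequency.
#' @export
effective_permittivity <- function(p, f) {
  UseMethod("effective_permittivity")
}

#' @export
effective_permittivity.homogeneous_particle <- function(p, f) {
  complex_permittivity(p$material, f)
}

#' @export
effective_permittivity.shelled_particle <- function(p, f) {
  core <- complex_permittivity(p$core_host, f)
  if (!p$core_premixed && p$lipid_fraction > 0) {
    core <- mg_mixture(core, complex_permittivity(p$lipid, f), p$lipid_fraction)
  }
  total_shell <- sum(vapply(p$shells, function(s) s$thickness, numeric(1)))
  r <- p$outer_radius - total_shell
  eff <- core
  for (s in p$shells) {
    r_out <- r + s$thickness
    eff <- shell_collapse(eff, complex_permittivity(s$material, f), r, r_out)
    r <- r_out
  }
  eff
}

#' Logarithmic frequency grid
#'
#' @param f_min,f_max Grid span in Hz, `0 < f_min < f_max`.
#' @param n Number of points, >= 2.
#' @return Numeric vector of `n` log-spaced frequencies.
#' @export
log_frequency_grid <- function(f_min = 250e3, f_max = 550e6, n = 200) {
  stopifnot(f_min > 0, f_max > f_min, n >= 2)
  10^seq(log10(f_min), log10(f_max), length.out = n)
}

#' Clausius-Mossotti spectrum of a particle in a medium
#'
#' Evaluates the complex CM factor of `particle` suspended in `medium` on a
#' frequency grid.
#'
#' @param particle A [shelled_particle()] or [homogeneous_particle()].
#' @param medium The suspending [material()].
#' @param frequencies Strictly ascending positive frequencies in Hz.
#' @return A tibble of class `cm_spectrum` with columns `frequency_hz`, `re`,
#'   `im`.
#' @examples
#' bead <- homogeneous_particle(1e-6, material(2.55, 0))
#' cm_spectrum(bead, material(78, 2.9), log_frequency_grid(n = 20))
#' @export
cm_spectrum <- function(particle, medium, frequencies = log_frequency_grid()) {
  stopifnot(inherits(medium, "dielectric_material"), is.numeric(frequencies))
  if (any(frequencies <= 0) || is.unsorted(frequencies, strictly = TRUE)) {
    stop("frequencies must be positive and strictly ascending", call. = FALSE)
  }
  fcm <- clausius_mossotti(
    effective_permittivity(particle, frequencies),
    complex_permittivity(medium, frequencies)
  )
  tibble::new_tibble(
    tibble::tibble(frequency_hz = frequencies, re = Re(fcm), im = Im(fcm)),
    class = "cm_spectrum"
  )
}

#' Extract a dielectric relaxation frequency from a CM spectrum
#'
#' Locates the first interfacial (Maxwell-Wagner) dispersion either at the
#' peak of the imaginary CM component (`"imag_peak"`) or at the maximum slope
#' of the real component against log-frequency (`"real_max_gradient"`). The
#' discrete maximum is refined by a three-point quadratic fit on log10(f).
#'
#' @param spectrum A [cm_spectrum()] tibble (>= 10 rows spanning the
#'   dispersion).
#' @param method `"imag_peak"` (global interior maximum of the imaginary
#'   component), `"real_max_gradient"` (maximum slope of the real component
#'   against log f), or `"first_imag_peak"` (lowest-frequency interior local
#'   maximum of the imaginary component, useful when two dispersions overlap
#'   and the lower-frequency one is wanted).
#' @return Relaxation frequency in Hz.
#' @export
relaxation_frequency <- function(spectrum,
                                 method = c("imag_peak", "real_max_gradient",
                                            "first_imag_peak")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(spectrum), all(c("frequency_hz", "re", "im") %in% names(spectrum)))
  if (nrow(spectrum) < 10) {
    stop("need at least 10 grid points to locate a relaxation", call. = FALSE)
  }
  lf <- log10(spectrum$frequency_hz)
  if (method %in% c("imag_peak", "first_imag_peak")) {
    y <- spectrum$im
    x <- lf
  } else {
    # centred derivative of Re against log10(f), on midpoint abscissae
    dre <- diff(spectrum$re) / diff(lf)
    x <- (lf[-1] + lf[-length(lf)]) / 2
    y <- dre
  }
  if (diff(range(y)) <= .Machine$double.eps * max(1, max(abs(y)))) {
    stop("no relaxation found: spectrum is flat", call. = FALSE)
  }
  if (method == "first_imag_peak") {
    n <- length(y)
    interior <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
    if (length(interior) == 0) {
      stop("no relaxation found: extremum lies on the grid boundary", call. = FALSE)
    }
    i <- interior[1]
  } else {
    i <- which.max(y)
    if (i == 1 || i == length(y)) {
      stop("no relaxation found: extremum lies on the grid boundary", call. = FALSE)
    }
  }
  10^quadratic_peak(x[i - 1], x[i], x[i + 1], y[i - 1], y[i], y[i + 1])
}

# Vertex abscissa of the parabola through three points; falls back to the
# middle point when the three are collinear.
quadratic_peak <- function(x1, x2, x3, y1, y2, y3) {
  d1 <- (y2 - y1) / (x2 - x1)
  d2 <- (y3 - y2) / (x3 - x2)
  curv <- (d2 - d1) / (x3 - x1)
  if (curv == 0) return(x2)
  xm <- (x1 + x2) / 2
  xp <- (x2 + x3) / 2
  # vertex of y = a x^2 + ...: derivative interpolates linearly between
  # midpoint slopes d1 at xm and d2 at xp
  xm + d1 * (xp - xm) / (d1 - d2)
}

#' Closed-form Maxwell-Wagner CM dispersion of a homogeneous sphere
#'
#' Single-Debye form of the CM factor for a homogeneous lossy sphere in a
#' lossy medium: `CM(f) = CM_inf + (CM_0 - CM_inf) / (1 + 1i * f/f_rel)` with
#' `tau = eps0 (eps_p + 2 eps_m) / (sigma_p + 2 sigma_m)` and
#' `f_rel = 1 / (2 pi tau)`; `CM_0` uses conductivities only and `CM_inf`
#' permittivities only. Used as the analytic reference for the numeric
#' spectrum path.
#'
#' @param particle_material,medium [material()]s of sphere and medium.
#' @param frequencies Frequencies in Hz.
#' @return List with `values` (complex CM factors) and `f_relaxation` (Hz).
#' @export
maxwell_wagner_sphere <- function(particle_material, medium, frequencies) {
  ep <- particle_material$relative_permittivity
  em <- medium$relative_permittivity
  sp <- particle_material$conductivity
  sm <- medium$conductivity
  cm0 <- (sp - sm) / (sp + 2 * sm)
  cminf <- (ep - em) / (ep + 2 * em)
  tau <- EPS0 * (ep + 2 * em) / (sp + 2 * sm)
  f_rel <- 1 / (2 * pi * tau)
  values <- cminf + (cm0 - cminf) / (1 + 1i * frequencies / f_rel)
  list(values = values, f_relaxation = f_rel)
}
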