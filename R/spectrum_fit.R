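# Population-spectrum normalisation and bounded compass-search fitting of the
# double-shell model by mean squared error.

#' Normalise a population-averaged current spectrum against a reference bead
#'
#' Converts mean differential currents for a cell population into
#' (scaled) Clausius-Mossotti units by multiplying the per-frequency
#' cell/bead current ratio by the modelled CM factor of the reference bead at
#' the reference frequency:
#' `observed(f) = f_CM_bead(f_ref) * cell(f) / bead(f_ref)`.
#'
#' @param cell_mean_current Complex vector: mean cell current per frequency.
#' @param bead_mean_current_at_ref Single complex: mean bead current at the
#'   reference frequency.
#' @param bead Reference [homogeneous_particle()] (default 5 um polystyrene).
#' @param medium Suspending [material()].
#' @param frequencies Measurement frequencies in Hz.
#' @param ref_frequency Reference frequency in Hz (default 80 MHz).
#' @param n_cells Number of cells averaged (bookkeeping).
#' @return A tibble of class `population_spectrum` with columns
#'   `frequency_hz`, `re`, `im`, and attributes `n_cells`, `bead_diameter_um`,
#'   `ref_frequency_hz`.
#' @export
normalize_population_spectrum <- function(cell_mean_current,
                                          bead_mean_current_at_ref,
                                          bead = homogeneous_particle(2.5e-6, polystyrene()),
                                          medium = seawater_medium(),
                                          frequencies,
                                          ref_frequency = 80e6,
                                          n_cells = NA_integer_) {
  stopifnot(
    is.complex(cell_mean_current) || is.numeric(cell_mean_current),
    length(bead_mean_current_at_ref) == 1,
    length(cell_mean_current) == length(frequencies)
  )
  if (abs(bead_mean_current_at_ref) == 0) {
    stop("reference bead current is zero; cannot normalise", call. = FALSE)
  }
  fcm_bead <- clausius_mossotti(
    effective_permittivity(bead, ref_frequency),
    complex_permittivity(medium, ref_frequency)
  )
  obs <- fcm_bead * as.complex(cell_mean_current) / as.complex(bead_mean_current_at_ref)
  population_spectrum(frequencies, obs,
    n_cells = n_cells,
    bead_diameter_um = bead$radius * 2e6,
    ref_frequency_hz = ref_frequency
  )
}

#' Construct a population spectrum table
#'
#' @param frequencies Frequencies in Hz, strictly ascending.
#' @param observed Complex observed values, one per frequency.
#' @param n_cells Number of cells averaged.
#' @param bead_diameter_um,ref_frequency_hz Reference-bead bookkeeping.
#' @return A `population_spectrum` tibble.
#' @export
population_spectrum <- function(frequencies, observed, n_cells = NA_integer_,
                                bead_diameter_um = 5, ref_frequency_hz = 80e6) {
  stopifnot(length(frequencies) == length(observed))
  if (any(frequencies <= 0) || is.unsorted(frequencies, strictly = TRUE)) {
    stop("frequencies must be positive and strictly ascending", call. = FALSE)
  }
  out <- tibble::tibble(
    frequency_hz = as.numeric(frequencies),
    re = Re(observed), im = Im(observed)
  )
  out <- tibble::new_tibble(out, class = "population_spectrum")
  attr(out, "n_cells") <- n_cells
  attr(out, "bead_diameter_um") <- bead_diameter_um
  attr(out, "ref_frequency_hz") <- ref_frequency_hz
  out
}

# Substitute named free parameters into a shelled-particle template.
# Recognised names: eps_i, sigma_i, lipid_fraction, eps_m, sigma_m,
# eps_s, sigma_s, radius.
apply_params <- function(template, params) {
  stopifnot(inherits(template, "shelled_particle"), length(template$shells) == 2)
  known <- c("eps_i", "sigma_i", "lipid_fraction", "eps_m", "sigma_m",
             "eps_s", "sigma_s", "radius")
  bad <- setdiff(names(params), known)
  if (length(bad) > 0) {
    stop("unknown model parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- as.list(params)
  get_or <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default
  shelled_particle(
    outer_radius = get_or("radius", template$outer_radius),
    core_host = material(
      get_or("eps_i", template$core_host$relative_permittivity),
      get_or("sigma_i", template$core_host$conductivity)
    ),
    lipid = template$lipid,
    lipid_fraction = get_or("lipid_fraction", template$lipid_fraction),
    shells = list(
      shell_layer(material(
        get_or("eps_m", template$shells[[1]]$material$relative_permittivity),
        get_or("sigma_m", template$shells[[1]]$material$conductivity)
      ), template$shells[[1]]$thickness),
      shell_layer(material(
        get_or("eps_s", template$shells[[2]]$material$relative_permittivity),
        get_or("sigma_s", template$shells[[2]]$material$conductivity)
      ), template$shells[[2]]$thickness)
    ),
    core_premixed = template$core_premixed
  )
}

#' Model-predicted spectrum for a parameter set
#'
#' Evaluates `scale * f_CM(f)` for the template particle with the named free
#' parameters substituted. The multiplicative scale absorbs the unnormalised
#' cell/bead volume ratio left on the y-axis by bead normalisation.
#'
#' @param params Named numeric vector of free parameters (`eps_i`, `sigma_i`,
#'   `lipid_fraction`, `eps_m`, `sigma_m`, `eps_s`, `sigma_s`, `radius`).
#' @param template A [shelled_particle()] providing all non-free values.
#' @param medium Suspending [material()].
#' @param frequencies Frequencies in Hz.
#' @param scale Multiplicative nuisance scale, > 0.
#' @return Complex vector of predicted values, one per frequency.
#' @export
model_prediction <- function(params, template, medium, frequencies, scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0)
  particle <- apply_params(template, params)
  s <- cm_spectrum(particle, medium, frequencies)
  scale * complex(real = s$re, imaginary = s$im)
}

#' Mean squared error between complex spectra
#'
#' Mean over frequencies of the squared Euclidean distance between the real
#' and imaginary components jointly:
#' `mean((Re pred - Re obs)^2 + (Im pred - Im obs)^2)`.
#'
#' @param pred,obs Complex vectors of equal length.
#' @return Non-negative scalar.
#' @export
mse_objective <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("prediction and observation lengths differ", call. = FALSE)
  }
  mean((Re(pred) - Re(obs))^2 + (Im(pred) - Im(obs))^2)
}

#' Bounded compass (pattern) search minimisation
#'
#' Derivative-free coordinate polling: from the incumbent, try +/- one step
#' along each coordinate (step expressed as a fraction of that coordinate's
#' bound range, clipped to the box); accept the first improving move; if a
#' full poll fails, halve the step. Stops when the step fraction falls below
#' `tolerance` or the evaluation budget is exhausted. The accepted objective
#' values are non-increasing by construction.
#'
#' @param objective Function of a named numeric vector returning a scalar.
#' @param lower,upper Named numeric bounds (same names, lower < upper).
#' @param init Named numeric start point strictly inside the box.
#' @param init_step Initial step as a fraction of each bound range.
#' @param tolerance Step fraction below which the search stops.
#' @param max_evals Objective evaluation budget.
#' @return List with `par` (argmin), `value`, `n_evals`, `converged` (TRUE if
#'   the step tolerance was reached), and `trace` (tibble of accepted
#'   iterates: `eval`, `step_frac`, `value`).
#' @export
compass_search <- function(objective, lower, upper, init,
                           init_step = 0.25, tolerance = 1e-6,
                           max_evals = 10000) {
  nm <- names(init)
  stopifnot(
    !is.null(nm), all(nm %in% names(lower)), all(nm %in% names(upper)),
    tolerance > 0, init_step > 0, max_evals >= 1
  )
  lower <- lower[nm]; upper <- upper[nm]
  stopifnot(all(lower < upper))
  if (any(init < lower | init > upper)) {
    stop("initial point lies outside the bounds", call. = FALSE)
  }
  range_ <- upper - lower
  x <- init
  fx <- objective(x)
  if (!is.finite(fx)) stop("objective is not finite at the initial point", call. = FALSE)
  n_evals <- 1L
  step <- init_step
  trace_eval <- n_evals; trace_step <- step; trace_val <- fx
  converged <- FALSE
  while (n_evals < max_evals) {
    if (step < tolerance) { converged <- TRUE; break }
    improved <- FALSE
    for (j in seq_along(x)) {
      for (sgn in c(1, -1)) {
        cand <- x
        cand[j] <- min(max(x[j] + sgn * step * range_[j], lower[j]), upper[j])
        if (cand[j] == x[j]) next
        fc <- objective(cand)
        n_evals <- n_evals + 1L
        if (is.finite(fc) && fc < fx) {
          x <- cand; fx <- fc; improved <- TRUE
          trace_eval <- c(trace_eval, n_evals)
          trace_step <- c(trace_step, step)
          trace_val <- c(trace_val, fx)
          break
        }
        if (n_evals >= max_evals) break
      }
      if (improved || n_evals >= max_evals) break
    }
    if (!improved) step <- step / 2
  }
  if (step < tolerance) converged <- TRUE
  list(
    par = x, value = fx, n_evals = n_evals, converged = converged,
    trace = tibble::tibble(eval = trace_eval, step_frac = trace_step, value = trace_val)
  )
}

#' Fit the double-shell model to a population spectrum
#'
#' Minimises the joint real+imaginary mean squared error between
#' `scale * f_CM(f; params)` and the observed spectrum by bounded
#' [compass_search()]. Bounds default to initial value / 10 and x 10 per free
#' parameter (fractions capped at 1); when `init` is omitted a blind start at
#' the log-midpoint of the bounds is used.
#'
#' @param spectrum A [population_spectrum()] (or any data frame with
#'   `frequency_hz`, `re`, `im`).
#' @param free Character vector of free parameter names (see
#'   [model_prediction()]).
#' @param template [shelled_particle()] carrying fixed values (default the
#'   fitted Isochrysis galbana model, [galbana_cell()]).
#' @param medium Suspending [material()].
#' @param init Optional named numeric vector of start values for the free
#'   parameters (and optionally `"scale"`).
#' @param lower,upper Optional named bounds overriding the defaults.
#' @param include_scale Fit a multiplicative nuisance scale.
#' @param init_step,tolerance,max_evals Search controls, see
#'   [compass_search()].
#' @return An object of class `shell_fit`: list with `fitted` (named vector),
#'   `scale`, `mse`, `n_evals`, `converged`, `trace`, `bounds`, and the
#'   inputs needed to reconstruct the prediction.
#' @export
fit_shell_model <- function(spectrum, free,
                            template = galbana_cell(),
                            medium = seawater_medium(),
                            init = NULL, lower = NULL, upper = NULL,
                            include_scale = TRUE,
                            init_step = 0.25, tolerance = 1e-6,
                            max_evals = 20000) {
  stopifnot(
    is.data.frame(spectrum),
    all(c("frequency_hz", "re", "im") %in% names(spectrum)),
    is.character(free), length(free) >= 1
  )
  obs <- complex(real = spectrum$re, imaginary = spectrum$im)
  frequencies <- spectrum$frequency_hz
  template_vals <- c(
    eps_i = template$core_host$relative_permittivity,
    sigma_i = template$core_host$conductivity,
    lipid_fraction = template$lipid_fraction,
    eps_m = template$shells[[1]]$material$relative_permittivity,
    sigma_m = template$shells[[1]]$material$conductivity,
    eps_s = template$shells[[2]]$material$relative_permittivity,
    sigma_s = template$shells[[2]]$material$conductivity,
    radius = template$outer_radius
  )
  bad <- setdiff(free, names(template_vals))
  if (length(bad) > 0) stop("unknown free parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  pars <- free
  if (include_scale) pars <- c(pars, "scale")
  ref <- c(template_vals, scale = 1)[pars]
  lo <- ref / 10
  hi <- ref * 10
  # volume fractions cannot exceed 1; permittivities cannot drop below 1
  if ("lipid_fraction" %in% pars) hi["lipid_fraction"] <- min(hi["lipid_fraction"], 0.95)
  for (pp in intersect(c("eps_i", "eps_m", "eps_s"), pars)) lo[pp] <- max(lo[pp], 1)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (is.null(init)) {
    x0 <- sqrt(lo * hi) # log-midpoint blind start
  } else {
    x0 <- ref
    x0[names(init)] <- init
  }
  obj <- function(x) {
    sc <- if (include_scale) x[["scale"]] else 1
    if (sc <= 0) return(Inf)
    pred <- model_prediction(x[setdiff(names(x), "scale")], template, medium,
                             frequencies, scale = sc)
    mse_objective(pred, obs)
  }
  res <- compass_search(obj, lo, hi, x0,
    init_step = init_step, tolerance = tolerance, max_evals = max_evals
  )
  fitted <- res$par[setdiff(names(res$par), "scale")]
  structure(
    list(
      fitted = fitted,
      scale = if (include_scale) unname(res$par[["scale"]]) else 1,
      mse = res$value, n_evals = res$n_evals, converged = res$converged,
      trace = res$trace,
      bounds = tibble::tibble(term = pars, lower = unname(lo), upper = unname(hi),
                              init = unname(x0)),
      free = free, include_scale = include_scale,
      template = template, medium = medium, spectrum = spectrum
    ),
    class = "shell_fit"
  )
}

#' @export
print.shell_fit <- function(x, ...) {
  cat("<shell_fit> double-shell model fit by compass search\n")
  cat(sprintf("  mse = %.4g after %d evaluations (%s)\n", x$mse, x$n_evals,
              if (x$converged) "converged" else "budget exhausted"))
  for (nm in names(x$fitted)) cat(sprintf("  %-14s %.6g\n", nm, x$fitted[[nm]]))
  if (x$include_scale) cat(sprintf("  %-14s %.6g\n", "scale", x$scale))
  invisible(x)
}

#' Tidy a shell-model fit
#'
#' @param x A `shell_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted term: `term`, `estimate`,
#'   `lower`, `upper`, `init`.
#' @method tidy shell_fit
#' @export
tidy.shell_fit <- function(x, ...) {
  est <- c(x$fitted, if (x$include_scale) c(scale = x$scale))
  dplyr::mutate(x$bounds, estimate = unname(est[.data$term]), .after = "term")
}

#' One-row summary of a shell-model fit
#'
#' @param x A `shell_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `mse`, `scale`, `n_evals`, `converged`,
#'   `n_freq`.
#' @method glance shell_fit
#' @export
glance.shell_fit <- function(x, ...) {
  tibble::tibble(
    mse = x$mse, scale = x$scale, n_evals = x$n_evals,
    converged = x$converged, n_freq = nrow(x$spectrum)
  )
}

#' Predicted spectrum of a fitted shell model
#'
#' @param object A `shell_fit`.
#' @param frequencies Frequencies in Hz (default: the fitted spectrum's grid).
#' @param ... Unused.
#' @return Tibble with `frequency_hz`, `re`, `im`.
#' @export
predict.shell_fit <- function(object, frequencies = NULL, ...) {
  if (is.null(frequencies)) frequencies <- object$spectrum$frequency_hz
  pred <- model_prediction(object$fitted, object$template, object$medium,
                           frequencies, scale = object$scale)
  tibble::tibble(frequency_hz = frequencies, re = Re(pred), im = Im(pred))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
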