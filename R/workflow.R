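# End-to-end orchestration: monoculture training runs, mixture analysis,
# multiclass and binary recovery evaluation.

#' Configure a synthetic mixture experiment
#'
#' Aggregates every setting of the two-stage protocol: per-class generators,
#' stock concentrations and mixing, calibration beads, detection limit, KNN
#' settings, and the seeds of each random stage.
#'
#' @param class_specs Named list of [class_gen_spec()]s (default
#'   [default_class_specs()]).
#' @param stocks Named stock concentrations in particles/uL (default 500 for
#'   every class; the equal-volumetric five-way mixture then carries 100/uL
#'   per class).
#' @param monoculture_concentration Concentration of each monodisperse
#'   training acquisition in particles/uL.
#' @param train_bead_concentration,mix_bead_concentration Calibration-bead
#'   spike concentrations for training runs and the mixture run.
#' @param flow_rate Flow rate in uL/min.
#' @param train_duration,mix_duration Acquisition durations in s.
#' @param bead_diameter Calibration-bead diameter in um.
#' @param lod Electrical-diameter limit of detection in um.
#' @param n_library Training-library size per class.
#' @param k KNN neighbourhood size.
#' @param seed_generation Base seed for the monoculture runs (run i uses
#'   `seed_generation + i - 1`).
#' @param seed_mixture Seed for the mixture run.
#' @param seed_subsample Seed for library subsampling.
#' @param recovery_truth `"realized"` (default): recovery denominators are
#'   the realised concentrations of detectable (above-LOD) events per true
#'   label, separating classifier error from Poisson sampling and detection
#'   loss; `"nominal"`: the diluted stock concentrations.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(class_specs = default_class_specs(),
                              stocks = NULL,
                              monoculture_concentration = 300,
                              train_bead_concentration = 100,
                              mix_bead_concentration = 200,
                              flow_rate = 30,
                              train_duration = 240,
                              mix_duration = 60,
                              bead_diameter = 2,
                              lod = 1.5,
                              n_library = 3000,
                              k = 11,
                              seed_generation = 1,
                              seed_mixture = 2,
                              seed_subsample = 1,
                              recovery_truth = c("realized", "nominal")) {
  if (is.null(stocks)) {
    stocks <- stats::setNames(rep(500, length(class_specs)), names(class_specs))
  }
  stopifnot(all(names(stocks) %in% names(class_specs)))
  structure(
    list(
      class_specs = class_specs, stocks = stocks,
      monoculture_concentration = monoculture_concentration,
      train_bead_concentration = train_bead_concentration,
      mix_bead_concentration = mix_bead_concentration,
      flow_rate = flow_rate, train_duration = train_duration,
      mix_duration = mix_duration, bead_diameter = bead_diameter,
      lod = lod, n_library = n_library, k = k,
      seed_generation = seed_generation, seed_mixture = seed_mixture,
      seed_subsample = seed_subsample,
      recovery_truth = match.arg(recovery_truth)
    ),
    class = "experiment_config"
  )
}

# Generate the monoculture runs and assemble the per-class feature lists
# (gated by the synthetic ground-truth label, standing in for manual gating
# of monodisperse populations).
build_training_features <- function(cfg) {
  labels <- names(cfg$class_specs)
  runs <- purrr::imap(cfg$class_specs, function(spec, lbl) {
    i <- match(lbl, labels)
    tab <- gen_monoculture(
      spec, cfg$monoculture_concentration,
      bead_concentration = cfg$train_bead_concentration,
      flow_rate = cfg$flow_rate, duration = cfg$train_duration,
      seed = cfg$seed_generation + i - 1
    )
    cal <- calibrate_size(dplyr::filter(tab, .data$true_label == "bead"),
                          cfg$bead_diameter)
    feats <- extract_features(tab, cal, lod = cfg$lod)
    list(table = tab, calibration = cal,
         features = dplyr::filter(feats, .data$true_label == lbl))
  })
  runs
}

# Calibrate on the mixture's own bead spike when present; otherwise
# transfer the calibration of the first training run (same instrument
# settings).
mixture_calibration <- function(mixture, runs, cfg) {
  beads <- dplyr::filter(mixture, .data$true_label == "bead")
  if (nrow(beads) >= 10) {
    calibrate_size(beads, cfg$bead_diameter)
  } else {
    runs[[1]]$calibration
  }
}

# Per-true-label realised concentrations of detectable events in a mixture,
# with the calibration-bead spike folded into the microplastic class (the
# beads are 2 um polystyrene, i.e. microplastics).
realized_detectable_truth <- function(features, volume_ul, report_classes) {
  counts <- table(features$true_label)
  truth <- stats::setNames(as.numeric(counts) / volume_ul, names(counts))
  if ("bead" %in% names(truth) && "microplastic" %in% report_classes) {
    truth["microplastic"] <- sum(truth[c("microplastic", "bead")], na.rm = TRUE)
  }
  truth[intersect(report_classes, names(truth))]
}

#' Run the mixed-culture classification experiment
#'
#' The full two-stage protocol: (1) generate one monodisperse acquisition
#' per class, calibrate the size and phase axes on its bead spike-ins,
#' extract (electrical diameter, HF phase) features above the detection
#' limit, and build balanced n-per-class training libraries; (2) generate an
#' equal-volumetric mixture of all stocks with calibration beads, classify
#' every detectable event with KNN, convert class counts to concentrations,
#' and score per-class recovery against the truth. Calibration-bead events
#' are counted with the microplastic class (they are 2 um polystyrene).
#'
#' @param cfg An [experiment_config()].
#' @return A list of class `mixture_experiment`: `recovery` (a
#'   [recovery_report()]), `concentrations`, `classified` (feature tibble
#'   with `.pred_class`), `model`, `library`, `mixture`, `training_runs`,
#'   `config`.
#' @export
run_mixed_culture_experiment <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  runs <- build_training_features(cfg)
  per_class <- purrr::map(runs, "features")
  library <- build_library(per_class, n = cfg$n_library, seed = cfg$seed_subsample)
  model <- knn_model(library, k = cfg$k)
  mixture <- gen_mixture(
    cfg$stocks, cfg$class_specs,
    bead_concentration = cfg$mix_bead_concentration,
    flow_rate = cfg$flow_rate, duration = cfg$mix_duration,
    seed = cfg$seed_mixture
  )
  cal <- mixture_calibration(mixture, runs, cfg)
  feats <- extract_features(mixture, cal, lod = cfg$lod)
  classified <- classify(model, feats)
  conc <- estimate_concentration(
    table(factor(classified$.pred_class, levels = names(cfg$class_specs))),
    flow_rate = cfg$flow_rate, duration = cfg$mix_duration
  )
  vol <- sampled_volume(mixture)
  truth <- if (cfg$recovery_truth == "realized") {
    realized_detectable_truth(feats, vol, names(cfg$class_specs))
  } else {
    nom <- attr(mixture, "nominal_truth")
    tr <- nom[intersect(names(cfg$class_specs), names(nom))]
    if ("microplastic" %in% names(tr)) {
      tr["microplastic"] <- tr["microplastic"] + nom[["bead"]]
    }
    tr
  }
  structure(
    list(
      recovery = recovery_report(conc, truth),
      concentrations = conc,
      classified = classified,
      model = model, library = library, mixture = mixture,
      training_runs = runs, config = cfg
    ),
    class = "mixture_experiment"
  )
}

#' @export
print.mixture_experiment <- function(x, ...) {
  cat("<mixture_experiment> KNN recovery of a synthetic mixed culture\n")
  print(as.data.frame(x$recovery), row.names = FALSE)
  invisible(x)
}

#' Default binary grouping: microplastics vs biological particles
#'
#' @param class_specs Named list of class specs.
#' @return Named character vector mapping each class to `"microplastic"` or
#'   `"biological"`.
#' @export
binary_grouping <- function(class_specs = default_class_specs()) {
  labels <- names(class_specs)
  stats::setNames(
    ifelse(labels == "microplastic", "microplastic", "biological"),
    labels
  )
}

#' Run the binary (microplastic vs biological) experiment
#'
#' Identical to [run_mixed_culture_experiment()] except that the training
#' library is pooled into two groups before training, as for screening field
#' samples: all phytoplankton classes form a single biological class.
#'
#' @param cfg An [experiment_config()].
#' @param grouping Named class -> group map (default [binary_grouping()]).
#' @return A list of class `mixture_experiment` with two report classes.
#' @export
run_binary_experiment <- function(cfg = experiment_config(),
                                  grouping = binary_grouping(cfg$class_specs)) {
  stopifnot(inherits(cfg, "experiment_config"))
  runs <- build_training_features(cfg)
  per_class <- purrr::map(runs, "features")
  library <- pool_binary(
    build_library(per_class, n = cfg$n_library, seed = cfg$seed_subsample),
    grouping
  )
  model <- knn_model(library, k = cfg$k)
  mixture <- gen_mixture(
    cfg$stocks, cfg$class_specs,
    bead_concentration = cfg$mix_bead_concentration,
    flow_rate = cfg$flow_rate, duration = cfg$mix_duration,
    seed = cfg$seed_mixture
  )
  cal <- mixture_calibration(mixture, runs, cfg)
  feats <- extract_features(mixture, cal, lod = cfg$lod)
  classified <- classify(model, feats)
  groups <- unique(unname(grouping))
  conc <- estimate_concentration(
    table(factor(classified$.pred_class, levels = groups)),
    flow_rate = cfg$flow_rate, duration = cfg$mix_duration
  )
  structure(
    list(
      recovery = NULL, concentrations = conc, classified = classified,
      model = model, library = library, mixture = mixture,
      training_runs = runs, config = cfg
    ),
    class = "mixture_experiment"
  )
}

#' Rectangular bead gate for unlabelled data
#'
#' Selects calibration-bead candidates from a feature tibble by a
#' rectangular gate: electrical diameter within `diameter_range` and HF
#' phase in the top quartile of the gated diameter slice (beads are solid
#' polystyrene, so they sit at high phase).
#'
#' @param features Feature tibble ([extract_features()] output).
#' @param diameter_range Diameter window in um (default `c(1.8, 2.2)`).
#' @return Logical vector marking gated rows.
#' @export
gate_beads <- function(features, diameter_range = c(1.8, 2.2)) {
  in_window <- features$electrical_diameter_um >= diameter_range[1] &
    features$electrical_diameter_um <= diameter_range[2]
  out <- rep(FALSE, nrow(features))
  if (!any(in_window)) return(out)
  q3 <- stats::quantile(features$phase_hf_rad[in_window], 0.75)
  out[in_window] <- features$phase_hf_rad[in_window] >= q3
  out
}
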