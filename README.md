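# cytoshell

Dual-frequency microfluidic impedance cytometry can count and classify
individual micron-scale particles in seawater — distinguishing solid
microplastics from living phytoplankton — without labels or optics. A
low-frequency (1 MHz) signal sizes each particle; a high-frequency
(500 MHz) signal probes its interior, where membranous cells and solid
plastics polarise very differently. cytoshell implements the computational
pipeline behind this measurement for people building or evaluating such
instruments:

* **Dielectric forward model** — complex permittivities
  (ε̃ = ε_r ε₀ − jσ/ω), Maxwell–Garnett mixing of lipid inclusions into
  cytoplasm, concentric-shell collapse of membrane and scale layers, and
  Clausius–Mossotti spectra
  f_CM = (ε̃_p − ε̃_m)/(ε̃_p + 2ε̃_m) with relaxation-frequency
  extraction.
* **Spectrum fitting** — bead-referenced normalisation of
  population-averaged spectra and bounded compass (pattern) search
  minimising the joint real+imaginary mean squared error of the
  double-shell model.
* **Event classification** — electrical diameter (cube root of the 1 MHz
  signal, bead-calibrated) and baselined 500 MHz phase; 1.5 um limit of
  detection; balanced n = 3000 training libraries; standardized-Euclidean
  KNN (k = 11, exhaustive, deterministic tie-break); concentrations and
  per-class recovery rates.
* **Synthetic instrument** — seeded generators for monocultures, mixtures,
  bead spike-ins, coliving-bacteria contamination, noisy population
  spectra, and simplified nine-electrode multipeak waveforms with
  matched-filter event detection.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()`/`predict()` methods and every result type has an
`autoplot()` or `plot_*()`.

## Worked example

Fit the double-shell model to a (noiseless, synthetic) population-averaged
spectrum of an *Isochrysis galbana* cell, starting 30% away from the
generating values:

```r
library(cytoshell)

gen <- gen_population_spectrum(
  galbana_cell(), seawater_medium(),
  frequencies = log_frequency_grid(250e3, 550e6, 60), noise_sd = 0
)
truth <- c(sigma_i = 1.12, eps_i = 63, eps_s = 13)
fit <- fit_shell_model(gen$spectrum, free = names(truth),
                       init = 1.3 * truth, include_scale = FALSE)
tidy(fit)
#> # A tibble: 3 × 5
#>   term    estimate lower upper  init
#>   <chr>      <dbl> <dbl> <dbl> <dbl>
#> 1 sigma_i     1.12 0.112  11.2  1.46
#> 2 eps_i      63.0  6.3   630   81.9
#> 3 eps_s      13.0  1.3   130   16.9
```

The inner-core conductivity (1.12 S/m), core permittivity (63) and
scale-layer permittivity (13) are recovered to within 0.001%: the bounded
compass search is exact on noiseless data. `autoplot(fit)` overlays the
fitted curve on the observed points.

Run the full synthetic mixed-culture experiment — five monocultures train
a KNN, an equal-volumetric mixture is classified, and each class's
recovered concentration is compared with the realised truth:

```r
res <- run_mixed_culture_experiment(experiment_config())
res$recovery
#>          class estimated_ul   true_ul recovery_pct
#>   microplastic    288.43333 302.80000     95.25539
#>      i_galbana     97.76667  98.60000     99.15483
#>     c_vulgaris     99.56667  99.93333     99.63309
#>    p_purpureum    101.30000 100.63333    100.66247
#>  synechococcus     35.76667  11.43333    312.82799
```

Four of the five classes are recovered to within 5% of truth. The
smallest class (*Synechococcus*, median 1.2 um, mostly below the 1.5 um
detection limit) is strongly *over*estimated: coliving bacteria from the
other cultures occupy the same corner of the (diameter, phase) plane and
are classified into it — the characteristic failure mode of this
measurement for near-LOD cells.

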