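---
title: "Shell-model impedance cytometry: models, fitting and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shell-model impedance cytometry: models, fitting and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(cytoshell)
library(dplyr)
```

cytoshell implements the computational side of dual-frequency microfluidic
impedance cytometry for telling microplastics apart from phytoplankton: a
multishell dielectric forward model with spectrum fitting, per-event
feature extraction and KNN classification scored by recovery rates, and a
synthetic-data generator that stands in for the instrument. This vignette
explains the models, the tunable parameters, and the design decisions, in
that order.

## The dielectric forward model

A particle suspended between facing microelectrodes perturbs the current in
proportion to its volume and its Clausius–Mossotti (CM) factor

$$f_\mathrm{CM}(\omega) =
  \frac{\tilde\varepsilon_p - \tilde\varepsilon_m}
       {\tilde\varepsilon_p + 2\tilde\varepsilon_m},
\qquad
\tilde\varepsilon = \varepsilon_r\varepsilon_0 - j\,\sigma/\omega,$$

with the particle's equivalent complex permittivity
$\tilde\varepsilon_p$ and the medium's $\tilde\varepsilon_m$. We use the
$e^{+j\omega t}$ time convention throughout, so conductive loss enters with
a negative imaginary part; the real part of $f_\mathrm{CM}$ is bounded in
$[-\tfrac12, 1]$ for passive materials, a property the test suite asserts
on randomly drawn particles.

A phytoplankton cell is modelled as concentric spheres. The inner core is
cytoplasm hosting lipid storage vesicles, mixed by the Maxwell–Garnett
effective-medium rule at volume fraction $L_I$; around it sit a thin plasma
membrane and, outermost, an organic scale layer. Each shell is collapsed
onto the growing core with the standard concentric-shell reduction

$$\tilde\varepsilon_{eq} = \tilde\varepsilon_s
  \frac{\gamma^3 + 2G}{\gamma^3 - G},\qquad
  \gamma = \frac{r_{out}}{r_{in}},\qquad
  G = \frac{\tilde\varepsilon_{in} - \tilde\varepsilon_s}
           {\tilde\varepsilon_{in} + 2\tilde\varepsilon_s},$$

applied innermost-first. The composition is verified in the tests against
an independent solution of the full electrostatic boundary-value problem
(a linear system in the per-layer dipole coefficients), to $10^{-10}$
relative.

`galbana_cell()` carries the fitted reference parameter set for an
*Isochrysis galbana* cell: core host $\varepsilon_I = 63$,
$\sigma_I = 1.12$ S/m with $L_I = 20\%$ lipid; membrane
$\varepsilon_M = 6$, $\sigma_M = 5\times10^{-4}$ S/m, 5 nm; scale layer
$\varepsilon_S = 13$, $\sigma_S = 9.9\times10^{-3}$ S/m, 100 nm. Defaults
the data do not pin down had to be chosen once: the suspending medium is
seawater-like ($\varepsilon_r = 78$, $\sigma = 2.9$ S/m as measured for the
culture medium), the lipid inclusions are oil-like
($\varepsilon_r = 2.2$, $\sigma = 10^{-6}$ S/m), and the cell radius
defaults to 2.5 um — population-averaged spectra constrain it only weakly,
and it can be set per call. The core values are read as the cytoplasm
*host* values with lipid mixed in on top; the alternative reading (already
mixed) is available via `core_premixed = TRUE`.

```{r cmspec}
spec <- cm_spectrum(galbana_cell(), seawater_medium(),
                    log_frequency_grid(250e3, 550e6, 200))
autoplot(spec)
```

### Dielectric relaxations

In a 2.9 S/m medium the cell looks insulating at low frequency
($\mathrm{Re}\,f_\mathrm{CM} \approx -0.5$) and disperses upward through
two overlapping interfacial (Maxwell–Wagner) relaxations: a
membrane/scale charging dispersion whose frequency scales like the inverse
of cell radius, and a cytoplasm/medium dispersion whose position is
essentially $\tau = \varepsilon_0(\varepsilon_{eff} +
2\varepsilon_m)/(\sigma_{eff} + 2\sigma_m)$ and therefore nearly
radius-independent. `relaxation_frequency()` refines the discrete
extremum with a three-point quadratic fit on $\log_{10} f$ and offers
three estimators: the global imaginary-part peak (`imag_peak`, the
default), the maximum slope of the real part against log-frequency
(`real_max_gradient`), and the lowest-frequency interior imaginary local
maximum (`first_imag_peak`) for when the two dispersions must be told
apart. On a homogeneous sphere all of these collapse onto the single-Debye
closed form (`maxwell_wagner_sphere()`), which the tests use as the
analytic oracle. For the reference cell model the global imaginary peak
falls at roughly 520 MHz and the lower charging dispersion near 70 MHz
(radius 2.5 um); both are computed, never asserted, and the choice of
estimator matters when comparing against figure-read values.

## Spectrum fitting

Population-averaged spectra are normalised against a reference bead
population (5 um polystyrene, measured at 80 MHz) by
`normalize_population_spectrum()`: the cell/bead current ratio is
multiplied by the bead's modelled CM factor at the reference frequency.
The normalised y-axis retains the unknown cell/bead volume ratio, so the
fit always offers a multiplicative nuisance scale.

`fit_shell_model()` minimises the mean squared error jointly over the real
and imaginary components — both carry information and the loss composition
is otherwise arbitrary — using a bounded compass (pattern) search:
coordinate-wise $\pm$ polling with step halving on a failed poll,
first-improvement acceptance, stopping when the step falls below a
relative tolerance (default $10^{-6}$) or the evaluation budget (default
20000) runs out. The search is deterministic; accepted objective values
are non-increasing by construction and the trace is returned so tests can
assert it. Bounds default to one decade either side of the reference value
for each free parameter (fractions capped below 1, permittivities floored
at 1); blind fits start at the log-midpoint of the bounds, self-consistency
fits start where the caller says. Only a subset of parameters is
identifiable from a single spectrum (core conductivity and permittivity,
scale-layer properties, and the scale factor); membrane permittivity and
the two thicknesses stay fixed by default, mirroring how such models are
fitted in practice.

```{r fit}
gen <- gen_population_spectrum(galbana_cell(), seawater_medium(),
                               frequencies = log_frequency_grid(250e3, 550e6, 60),
                               noise_sd = 0)
truth <- c(sigma_i = 1.12, eps_i = 63, eps_s = 13)
fit <- fit_shell_model(gen$spectrum, free = names(truth),
                       init = 1.3 * truth, include_scale = FALSE)
tidy(fit)
glance(fit)
```

## Per-event features and classification

Each detected particle yields a dual-frequency record. Two features are
extracted: the **electrical diameter**, the cube root of the 1 MHz real
signal calibrated so the 2 um bead-spike median maps exactly to 2 um, and
the **500 MHz phase**, the four-quadrant angle of the high-frequency
vector minus the run-level baseline. The baseline is the median
calibration-bead phase, which is why the calibration object carries a
third field beyond the nominal diameter and median signal. Events with an
electrical diameter below the 1.5 um limit of detection are discarded;
the boundary itself is kept, since only values strictly below the
threshold are unreliable.

Classification is k-nearest-neighbours (default $k = 11$, selectable by
stratified 10-fold cross-validation via `select_k()`) with the
standardized Euclidean metric: one pooled standard deviation per feature,
computed over the whole training library, exhaustive search, no weighting.
Training libraries are balanced to $n = 3000$ points per class by seeded
subsampling. Vote ties are broken by the class of the nearest neighbour
among the tied classes — a deterministic rule chosen so the classifier is
exactly reproducible and testable against a brute-force oracle (MATLAB's
`fitcknn` breaks ties differently, toward the smallest class index, so
individual tie events may differ between implementations).

Counts become concentrations through the sampled volume
(flow rate $\times$ duration / 60, in uL; no coincidence correction), and
accuracy is reported as the **recovery rate**, 100 x classified / true
concentration per class.

## The synthetic instrument

`gen_monoculture()` and `gen_mixture()` emulate the data the instrument
produces, with every stochastic element seeded:

* event counts are Poisson at concentration x volume with uniform
  timestamps (a Poisson process conditioned on its count);
* diameters are lognormal per class — median and geometric SD are the two
  tunables — optionally a mixture of subpopulations sharing the GSD, which
  is how the multimodal 2/3/5/8 um microplastic mix is expressed;
* the 1 MHz real signal is (d/2 um)^3 bead-volume units with 5%
  multiplicative lognormal noise (monodisperse bead CVs of a few percent
  are typical of such systems);
* the HF phase is a class offset plus Gaussian noise of SD
  $c/d^3$ with $c = 0.4$ rad um^3: phase precision is signal-limited, and
  the signal scales with particle volume, reproducing the broadening of
  phase distributions toward small diameters;
* phytoplankton classes carry coliving-bacteria contamination (default
  10% of class events, median 1.3 um) — non-axenic cultures always do;
* 2 um polystyrene calibration beads are spiked at 100/uL into
  monocultures and 200/uL into mixtures.

The default five classes place the microplastic mix at a high phase
offset (0.30 rad, shared with the beads — they are the same material) and
the four phytoplankton classes at low offsets (0.10/0.12/0.08/0.14 rad
for *I. galbana* at 5 um, *C. vulgaris* at 3.5 um, *P. purpureum* at 6 um
and *Synechococcus* at 1.2 um median). These offsets and spreads were
chosen once, on physical grounds (solid low-loss plastics polarise very
differently from membranous cells at 500 MHz, while different membranous
cells are similar), to reproduce the qualitative feature-plane layout of
the real experiment: plastics cleanly separable, the three larger
phytoplankton overlapping partially in size, and *Synechococcus* largely
below the detection limit and entangled with bacteria. They are
configurable and are not fitted to any measured data; passing tests on
these defaults demonstrates the pipeline's behaviour under the assumed
statistical structure (lognormal sizes, Gaussian phase noise, independent
events), not performance on real seawater, which also contains silt,
bubbles, and particle classes never seen in training.

The simplified waveform module generates the multipeak transit signal of
a nine-pair facing-electrode array as alternating-polarity Gaussian lobes
(default pitch 60 um, 230 ksamples/s, lobe SD 25 us) and recovers events
by matched filtering over a coarse log-spaced velocity grid, followed by
golden-section refinement of velocity and least-squares amplitude
estimation. Gain is a single multiplicative factor — no position
dependence, no electric-field modelling — because its role here is to
close the loop from waveform to (amplitude, velocity) pairs, not to model
electrode physics.

## The two experiments

`run_mixed_culture_experiment()` chains the whole protocol: five
monoculture acquisitions (240 s each at 300 particles/uL, enough that the
partially-sub-LOD class still yields over 3000 detectable training
events), per-run bead calibration, LOD filtering, balanced library
construction, KNN training, an equal-volumetric mixture of the five
stocks (500/uL each, so 100/uL per class) analysed for 60 s, and a
recovery report. `run_binary_experiment()` pools the phytoplankton classes
into a single biological group first, the configuration used for
screening field samples.

Two accounting choices matter:

* **Calibration beads count as microplastics.** The 2 um spike-in beads
  are polystyrene, indistinguishable from the 2 um component of the
  plastic mix, so their realised concentration is added to the
  microplastic truth rather than treated as a separate class.
* **Recovery defaults to realised, detectable truth**: the denominator is
  the concentration of generated events of that class that survive the
  detection limit, so the recovery isolates classifier error from Poisson
  sampling error and detection loss. This matches how true concentrations
  are established in practice (by gating the same instrument's monoculture
  data, which is itself LOD-cropped). Nominal stock-dilution truth is
  available with `recovery_truth = "nominal"`. Bacteria are deliberately
  absent from both truth and training — they are contaminants the
  experimenter does not know about — which is exactly why the smallest
  phytoplankton class is overestimated: bacteria events land in its region
  of the feature plane and are classified into it.

```{r experiment, eval = FALSE}
res <- run_mixed_culture_experiment(experiment_config())
res$recovery
autoplot(res$recovery)
```

(The full-size run takes about half a minute; it is exercised by the test
suite and the acceptance script rather than knitted here.)

## Numerical choices and degenerate inputs

* Relaxation peaks: 3-point quadratic interpolation on $\log_{10} f$;
  flat spectra and boundary extrema raise errors rather than return
  numbers.
* The CM denominator, zero bead currents, non-positive sizing signals and
  zero HF vectors are rejected or flagged per event rather than silently
  propagated.
* Compass search clips proposals to the box; a non-finite objective at
  the start is an error, later non-finite proposals are simply never
  accepted.
* Mixture calibration falls back to the first training run's calibration
  when the mixture contains no bead spike (calibration transfer).
* Cross-validation folds, library subsampling and all generators take
  explicit integer seeds; identical seeds give byte-identical outputs.

## Known limitations

* The forward model ignores electrode geometry, double-layer effects and
  any size dependence beyond the volume factor; the CM factor is the
  whole story here.
* Fits report point estimates and the final MSE only — no uncertainty
  quantification, and no global-optimality guarantee beyond the bounded
  search.
* The generator's class parameters are plausible stand-ins, not fitted
  values; absolute recovery numbers on synthetic mixtures characterise
  the pipeline under the generator's assumptions only.
* Velocity estimation assumes the simplified lobe shape; real waveforms
  have position-dependent gain the template ignores.
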