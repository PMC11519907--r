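test_that("complex permittivity follows the e^{+jwt} lossy-dielectric form", {
  # lossless media are purely real at any frequency
  expect_equal(complex_permittivity(material(78, 0), 1e3), 78 * 8.854e-12 + 0i)
  expect_equal(complex_permittivity(material(2.55, 0), 500e6), 2.55 * 8.854e-12 + 0i)
  # conductive loss enters as -sigma/(2 pi f) on the imaginary axis
  v <- complex_permittivity(material(78, 2.9), 1e6)
  expect_equal(Im(v), -2.9 / (2 * pi * 1e6))
  expect_equal(Re(v), 78 * 8.854e-12)
  expect_error(complex_permittivity(material(78, 2.9), 0), "positive")
  expect_error(complex_permittivity(material(78, 2.9), -1e6), "positive")
})

test_that("Clausius-Mossotti factor has the matched, insulating and 2:1 limits", {
  em <- complex_permittivity(material(78, 2.9), 1e6)
  expect_equal(clausius_mossotti(em, em), 0 + 0i)
  # insulating sphere in a conductive medium at low frequency -> -1/2
  ep <- complex_permittivity(material(2.55, 0), 1e3)
  em_lf <- complex_permittivity(material(78, 2.9), 1e3)
  expect_equal(Re(clausius_mossotti(ep, em_lf)), -0.5, tolerance = 1e-6)
  # eps_p = 2 eps_m -> (2-1)/(2+2) = 1/4 by hand
  expect_equal(clausius_mossotti(2 * em, em), 0.25 + 0i)
  expect_error(clausius_mossotti(-2 + 0i, 1 + 0i), "denominator")
})

test_that("Maxwell-Garnett mixing has exact endpoints and matches the alternative form", {
  host <- complex_permittivity(material(63, 1.12), 1e7)
  inc <- complex_permittivity(material(2.2, 1e-6), 1e7)
  expect_identical(mg_mixture(host, inc, 0), host)
  expect_equal(mg_mixture(host, inc, 1), inc)
  for (phi in c(0.05, 0.2, 0.5, 0.8)) {
    expect_equal(mg_mixture(host, inc, phi), mg_alternative(host, inc, phi),
                 tolerance = 1e-12)
  }
  expect_error(mg_mixture(host, inc, 1.2), "\\[0, 1\\]")
  expect_error(mg_mixture(host, inc, -0.1), "\\[0, 1\\]")
})

test_that("shell collapse reduces to the core for trivial shells", {
  inner <- complex_permittivity(material(63, 1.12), 1e6)
  expect_equal(shell_collapse(inner, inner, 1e-6, 1.5e-6), inner,
               tolerance = 1e-12)
  shell <- complex_permittivity(material(6, 5e-4), 1e6)
  expect_equal(shell_collapse(inner, shell, 1e-6, 1e-6 * (1 + 1e-9)), inner,
               tolerance = 1e-6)
  expect_error(shell_collapse(inner, shell, 1e-6, 1e-6), "r_in < r_out")
})

test_that("layer composition agrees with the electrostatic boundary-value oracle", {
  set.seed(42)
  for (rep in 1:20) {
    eps_core <- cplx_eps(runif(1, 2, 80), runif(1, 0, 3), 1e7)
    eps_s1 <- cplx_eps(runif(1, 2, 80), runif(1, 0, 3), 1e7)
    eps_s2 <- cplx_eps(runif(1, 2, 80), runif(1, 0, 3), 1e7)
    r <- sort(runif(3, 0.5e-6, 5e-6))
    two_step <- shell_collapse(
      shell_collapse(eps_core, eps_s1, r[1], r[2]),
      eps_s2, r[2], r[3]
    )
    eps_med <- cplx_eps(78, 2.9, 1e7)
    cm_pkg <- clausius_mossotti(two_step, eps_med)
    cm_ref <- cm_bvp(list(eps_core, eps_s1, eps_s2), r, eps_med)
    expect_equal(cm_pkg, cm_ref, tolerance = 1e-10)
  }
})

test_that("effective permittivity handles degenerate and homogeneous particles", {
  core <- material(63, 1.12)
  degenerate <- shelled_particle(
    2.5e-6, core, lipid_oil(), lipid_fraction = 0,
    shells = list(shell_layer(core, 5e-9), shell_layer(core, 100e-9))
  )
  f <- c(1e6, 1e8)
  expect_equal(effective_permittivity(degenerate, f),
               complex_permittivity(core, f), tolerance = 1e-12)
  bead <- homogeneous_particle(1e-6, material(2.55, 0))
  eb <- effective_permittivity(bead, c(1e5, 1e7, 5e8))
  expect_true(all(eb == eb[1]))  # lossless solid: frequency independent
})

test_that("the fitted cell model is near-insulating at 1 MHz in seawater", {
  s <- cm_spectrum(galbana_cell(), seawater_medium(), log_frequency_grid(n = 50))
  expect_lt(abs(s$re[which.min(abs(s$frequency_hz - 1e6))] - (-0.5)), 0.05)
  # rises through a dispersion toward high frequency
  expect_gt(s$re[50], s$re[1] + 0.1)
})

test_that("CM spectrum of a matched particle is identically zero", {
  med <- material(40, 1.5)
  p <- homogeneous_particle(2e-6, med)
  s <- cm_spectrum(p, med, log_frequency_grid(n = 20))
  expect_true(all(abs(s$re) < 1e-14 & abs(s$im) < 1e-14))
})

test_that("homogeneous-sphere spectra equal the single-Debye closed form", {
  med <- seawater_medium()
  set.seed(7)
  for (rep in 1:10) {
    pm <- material(runif(1, 2, 80), runif(1, 0, 2))
    grid <- log_frequency_grid(1e4, 1e10, 40)
    s <- cm_spectrum(homogeneous_particle(1e-6, pm), med, grid)
    mw <- maxwell_wagner_sphere(pm, med, grid)
    expect_equal(complex(real = s$re, imaginary = s$im), mw$values,
                 tolerance = 1e-10)
  }
})

test_that("real CM component stays within the passive bounds [-0.5, 1]", {
  med <- seawater_medium()
  set.seed(11)
  for (rep in 1:25) {
    p <- shelled_particle(
      runif(1, 1e-6, 5e-6),
      material(runif(1, 2, 80), runif(1, 0, 3)), lipid_oil(),
      lipid_fraction = runif(1, 0, 0.5),
      shells = list(
        shell_layer(material(runif(1, 2, 80), runif(1, 0, 1)), 5e-9),
        shell_layer(material(runif(1, 2, 80), runif(1, 0, 1)), 100e-9)
      )
    )
    s <- cm_spectrum(p, med, log_frequency_grid(1e4, 1e10, 50))
    expect_true(all(s$re >= -0.5 - 1e-9 & s$re <= 1 + 1e-9))
  }
})

test_that("low/high frequency limits reduce to conductivity-only and permittivity-only contrasts", {
  med <- seawater_medium()
  pm <- material(10, 0.05)
  mw <- maxwell_wagner_sphere(pm, med, 1)
  f_rel <- mw$f_relaxation
  grid <- sort(c(f_rel * 1e-3, f_rel * 1e3))
  s <- cm_spectrum(homogeneous_particle(1e-6, pm), med, grid)
  cm_sigma <- (0.05 - 2.9) / (0.05 + 2 * 2.9)
  cm_eps <- (10 - 78) / (10 + 2 * 78)
  expect_equal(s$re[1], cm_sigma, tolerance = 0.01)
  expect_equal(s$re[2], cm_eps, tolerance = 0.01)
})

test_that("relaxation extraction matches the analytic Maxwell-Wagner frequency", {
  med <- seawater_medium()
  pm <- material(10, 0.05)
  grid <- log_frequency_grid(1e5, 1e11, 60)
  s <- cm_spectrum(homogeneous_particle(1e-6, pm), med, grid)
  f_hat <- relaxation_frequency(s, "imag_peak")
  f_true <- maxwell_wagner_sphere(pm, med, 1)$f_relaxation
  expect_equal(f_hat, f_true, tolerance = 0.02)
  # max-gradient estimator locates the same dispersion (looser: halved grid
  # resolution on the derivative)
  expect_equal(relaxation_frequency(s, "real_max_gradient"), f_true,
               tolerance = 0.1)
})

test_that("flat or boundary-peaked spectra raise a no-relaxation error", {
  med <- material(40, 1.5)
  flat <- cm_spectrum(homogeneous_particle(2e-6, med), med,
                      log_frequency_grid(n = 20))
  expect_error(relaxation_frequency(flat), "flat|boundary")
  pm <- material(10, 0.05)
  f_true <- maxwell_wagner_sphere(pm, med, 1)$f_relaxation
  below <- cm_spectrum(homogeneous_particle(1e-6, pm), med,
                       log_frequency_grid(f_true * 10, f_true * 1000, 20))
  expect_error(relaxation_frequency(below), "boundary")
})

test_that("grid validation rejects unsorted or nonpositive frequencies", {
  bead <- homogeneous_particle(1e-6, polystyrene())
  expect_error(cm_spectrum(bead, seawater_medium(), c(1e6, 1e5)), "ascending")
  expect_error(cm_spectrum(bead, seawater_medium(), c(-1, 1e5)), "positive")
})
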