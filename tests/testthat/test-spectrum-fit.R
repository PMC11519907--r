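grid60 <- log_frequency_grid(250e3, 550e6, 60)

test_that("bead normalisation inverts a constructed current synthesis", {
  med <- seawater_medium()
  bead <- homogeneous_particle(2.5e-6, polystyrene())
  cell <- galbana_cell()
  fcm_cell <- {
    s <- cm_spectrum(cell, med, grid60)
    complex(real = s$re, imaginary = s$im)
  }
  fcm_bead_ref <- {
    s <- cm_spectrum(bead, med, c(80e6, 81e6))
    complex(real = s$re, imaginary = s$im)[1]
  }
  k <- 3.7  # arbitrary cell/bead volume ratio
  currents <- k * fcm_cell / fcm_bead_ref
  out <- normalize_population_spectrum(
    currents, 1 + 0i, bead = bead, medium = med,
    frequencies = grid60, ref_frequency = 80e6
  )
  expect_equal(complex(real = out$re, imaginary = out$im), k * fcm_cell,
               tolerance = 1e-12)
  # self-normalisation: identical cell and bead currents at the reference
  self <- normalize_population_spectrum(
    1 + 0i, 1 + 0i, bead = bead, medium = med,
    frequencies = 80e6, ref_frequency = 80e6
  )
  expect_equal(complex(real = self$re, imaginary = self$im), fcm_bead_ref)
  expect_error(
    normalize_population_spectrum(currents, 0 + 0i, bead = bead, medium = med,
                                  frequencies = grid60),
    "zero"
  )
})

test_that("model prediction is the scaled CM spectrum and is linear in scale", {
  med <- seawater_medium()
  tmpl <- galbana_cell()
  s <- cm_spectrum(tmpl, med, grid60)
  p1 <- model_prediction(c(sigma_i = 1.12), tmpl, med, grid60, scale = 1)
  expect_equal(p1, complex(real = s$re, imaginary = s$im), tolerance = 1e-14)
  p2 <- model_prediction(c(sigma_i = 1.12), tmpl, med, grid60, scale = 2)
  expect_equal(p2, 2 * p1)
  expect_error(model_prediction(c(bogus = 1), tmpl, med, grid60), "unknown")
})

test_that("model prediction agrees with the independent mixing + BVP path", {
  med <- seawater_medium()
  tmpl <- galbana_cell()
  f <- c(1e6, 5e7, 5e8)
  pred <- model_prediction(c(eps_i = 63, sigma_i = 1.12), tmpl, med, f)
  ref <- vapply(f, function(ff) {
    host <- cplx_eps(63, 1.12, ff)
    core <- mg_alternative(host, cplx_eps(2.2, 1e-6, ff), 0.20)
    cm_bvp(
      list(core, cplx_eps(6, 5e-4, ff), cplx_eps(13, 9.9e-3, ff)),
      c(2.5e-6 - 105e-9, 2.5e-6 - 100e-9, 2.5e-6),
      cplx_eps(78, 2.9, ff)
    )
  }, complex(1))
  expect_equal(pred, ref, tolerance = 1e-10)
})

test_that("the MSE objective has its closed forms and is order invariant", {
  expect_identical(mse_objective(1:5 + 0i, 1:5 + 0i), 0)
  obs <- complex(real = rnorm(8), imaginary = rnorm(8))
  d <- 0.3
  expect_equal(mse_objective(obs + d, obs), d^2)
  set.seed(3)
  pred <- complex(real = rnorm(20), imaginary = rnorm(20))
  obs2 <- complex(real = rnorm(20), imaginary = rnorm(20))
  loop <- 0
  for (i in 1:20) {
    loop <- loop + (Re(pred[i]) - Re(obs2[i]))^2 + (Im(pred[i]) - Im(obs2[i]))^2
  }
  expect_equal(mse_objective(pred, obs2), loop / 20)
  o <- sample(20)
  expect_equal(mse_objective(pred[o], obs2[o]), mse_objective(pred, obs2))
  expect_error(mse_objective(pred, obs2[1:3]), "length")
})

test_that("compass search solves a 1-D bowl and descends monotonically", {
  a <- 0.37
  res <- compass_search(
    function(x) (x[["x"]] - a)^2,
    lower = c(x = a - 1), upper = c(x = a + 1), init = c(x = a + 0.9),
    tolerance = 1e-8
  )
  expect_true(res$converged)
  expect_equal(unname(res$par[["x"]]), a, tolerance = 1e-6)
  # 2-D curved valley: accepted objective values never increase
  rosen <- function(x) (1 - x[["a"]])^2 + 5 * (x[["b"]] - x[["a"]]^2)^2
  res2 <- compass_search(
    rosen, lower = c(a = -2, b = -2), upper = c(a = 2, b = 2),
    init = c(a = -1.5, b = 1.5), tolerance = 1e-6, max_evals = 5000
  )
  expect_true(all(diff(res2$trace$value) <= 0))
  expect_lte(res2$value, rosen(c(a = -1.5, b = 1.5)))
  expect_true(all(res2$par >= c(a = -2, b = -2) & res2$par <= c(a = 2, b = 2)))
  expect_error(
    compass_search(function(x) x[["x"]]^2, c(x = 0), c(x = 1), c(x = 2)),
    "outside"
  )
})

test_that("noiseless fits recover the generating parameters", {
  gen <- gen_population_spectrum(galbana_cell(), frequencies = grid60,
                                 noise_sd = 0)
  truth <- c(sigma_i = 1.12, eps_i = 63, eps_s = 13)
  # already-optimal start
  fit0 <- fit_shell_model(gen$spectrum, free = names(truth), init = truth,
                          include_scale = FALSE)
  expect_true(fit0$converged)
  expect_lt(fit0$mse, 1e-12)
  expect_equal(fit0$fitted[names(truth)], truth, tolerance = 1e-3)
  # perturbed start within +/-30%: recovery within 1% per parameter
  fit1 <- fit_shell_model(gen$spectrum, free = names(truth),
                          init = truth * c(1.3, 0.75, 1.25),
                          include_scale = FALSE)
  expect_equal(fit1$fitted[names(truth)], truth, tolerance = 0.01)
  expect_true(all(diff(fit1$trace$value) <= 0))
  b <- tidy(fit1)
  expect_true(all(b$estimate >= b$lower & b$estimate <= b$upper))
})

test_that("scale and parameters are jointly identifiable on scaled spectra", {
  gen <- gen_population_spectrum(galbana_cell(), frequencies = grid60,
                                 noise_sd = 0, scale = 2.4)
  fit <- fit_shell_model(gen$spectrum, free = "sigma_i",
                         init = c(sigma_i = 1.5, scale = 1.8),
                         include_scale = TRUE)
  expect_equal(unname(fit$fitted[["sigma_i"]]), 1.12, tolerance = 0.01)
  expect_equal(fit$scale, 2.4, tolerance = 0.01)
  g <- glance(fit)
  expect_equal(g$n_freq, 60)
  expect_lt(g$mse, 1e-10)
})

test_that("median recovery under 1% measurement noise stays within 10%", {
  recovered <- vapply(1:10, function(s) {
    gen <- gen_population_spectrum(
      galbana_cell(), frequencies = log_frequency_grid(250e3, 550e6, 40),
      noise_sd = 0.01 * sqrt(10000), n_cells = 10000, seed = 100 + s
    )
    fit <- fit_shell_model(gen$spectrum, free = "sigma_i",
                           init = c(sigma_i = 1.4), include_scale = FALSE,
                           tolerance = 1e-5, max_evals = 2000)
    fit$fitted[["sigma_i"]]
  }, numeric(1))
  expect_lt(abs(stats::median(recovered) - 1.12) / 1.12, 0.10)
})

test_that("fitted values always lie inside their bounds (random perturbed fits)", {
  gen <- gen_population_spectrum(galbana_cell(), frequencies = grid60,
                                 noise_sd = 0.5 * sqrt(10000), seed = 5)
  for (s in 1:3) {
    set.seed(s)
    init <- c(sigma_i = 1.12, eps_s = 13) * runif(2, 0.8, 1.2)
    fit <- fit_shell_model(gen$spectrum, free = c("sigma_i", "eps_s"),
                           init = init, include_scale = FALSE,
                           tolerance = 1e-4, max_evals = 1500)
    b <- tidy(fit)
    expect_true(all(b$estimate >= b$lower & b$estimate <= b$upper))
    expect_gte(fit$mse, 0)
  }
})

test_that("spectra round-trip through CSV", {
  s <- cm_spectrum(galbana_cell(), seawater_medium(), grid60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$re, s$re, tolerance = 1e-12)
  expect_equal(back$frequency_hz, s$frequency_hz, tolerance = 1e-12)
})
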