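# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

EPS0_T <- 8.854e-12

# Complex permittivity written independently (same physical convention).
cplx_eps <- function(eps_r, sigma, f) {
  complex(real = eps_r * EPS0_T, imaginary = -sigma / (2 * pi * f))
}

# Dipole coefficient of a concentric multishell sphere from the full
# electrostatic boundary-value problem: regions are core + shells (complex
# permittivities innermost first, outer radii `radii`), embedded in
# `eps_med`, unit external field. Potential in region j is
# (A_j r + B_j / r^2) cos(theta); continuity of potential and of
# eps * d(potential)/dr at every interface gives a linear system whose
# exterior dipole term P yields the Clausius-Mossotti factor P / r_N^3.
cm_bvp <- function(eps_layers, radii, eps_med) {
  n <- length(eps_layers)
  stopifnot(length(radii) == n)
  radii <- radii / radii[n]          # scale invariances of the CM factor
  eps <- c(unlist(eps_layers), eps_med) / eps_med
  eps_med <- 1 + 0i
  # unknowns: A_1, (A_2, B_2), ..., (A_n, B_n), P  -> 2n unknowns
  idx_A <- function(j) if (j == 1) 1L else 2L * (j - 1L)
  idx_B <- function(j) 2L * (j - 1L) + 1L  # only valid for j >= 2
  M <- matrix(0 + 0i, 2 * n, 2 * n)
  rhs <- rep(0 + 0i, 2 * n)
  row <- 0L
  for (j in seq_len(n)) {
    r <- radii[j]
    # inner-side coefficients
    a_in <- idx_A(j)
    b_in <- if (j >= 2) idx_B(j) else NA_integer_
    row <- row + 1L
    M[row, a_in] <- r
    if (!is.na(b_in)) M[row, b_in] <- 1 / r^2
    if (j < n) {
      M[row, idx_A(j + 1)] <- -r
      M[row, idx_B(j + 1)] <- -1 / r^2
    } else {
      M[row, 2L * n] <- -1 / r^2  # P
      rhs[row] <- -r              # from exterior term -r
    }
    row <- row + 1L
    M[row, a_in] <- eps[j]
    if (!is.na(b_in)) M[row, b_in] <- -2 * eps[j] / r^3
    if (j < n) {
      M[row, idx_A(j + 1)] <- -eps[j + 1]
      M[row, idx_B(j + 1)] <- 2 * eps[j + 1] / r^3
    } else {
      M[row, 2L * n] <- 2 * eps_med / r^3
      rhs[row] <- -eps_med
    }
  }
  sol <- solve(M, rhs)
  sol[2L * n] / radii[n]^3
}

# Maxwell-Garnett in the alternative algebraic arrangement.
mg_alternative <- function(host, inclusion, phi) {
  host * (2 * (1 - phi) * host + (1 + 2 * phi) * inclusion) /
    ((2 + phi) * host + (1 - phi) * inclusion)
}

# Brute-force standardized-Euclidean KNN with the package's tie-break
# contract, written as plain loops over all pairs.
knn_oracle <- function(train_x, train_class, query_x, k, stds) {
  out <- character(nrow(query_x))
  for (i in seq_len(nrow(query_x))) {
    d2 <- numeric(nrow(train_x))
    for (t in seq_len(nrow(train_x))) {
      s <- 0
      for (f in seq_len(ncol(train_x))) {
        s <- s + ((query_x[i, f] - train_x[t, f]) / stds[f])^2
      }
      d2[t] <- s
    }
    nn <- order(d2)[1:k]
    counts <- table(train_class[nn])
    winners <- names(counts)[counts == max(counts)]
    if (length(winners) == 1) {
      out[i] <- winners
    } else {
      for (t in nn) {
        if (train_class[t] %in% winners) { out[i] <- train_class[t]; break }
      }
    }
  }
  out
}

# Small deterministic feature tibble for classifier tests.
toy_features <- function(d, ph, label = NA_character_) {
  tibble::tibble(
    electrical_diameter_um = d, phase_hf_rad = ph,
    true_label = rep_len(label, length(d))
  )
}

# Event table whose electrical diameters are exact by construction:
# re_1mhz = (d/2)^3 bead-volume units, HF vector at the given phase.
exact_event_table <- function(d, phase = 0.3, label = "x", duration = 10) {
  n <- length(d)
  event_table(
    tibble::tibble(
      timestamp_s = seq_len(n) * duration / (n + 1),
      re_1mhz = (d / 2)^3, im_1mhz = 0,
      re_500mhz = (d / 2)^3 * cos(rep_len(phase, n)),
      im_500mhz = (d / 2)^3 * sin(rep_len(phase, n)),
      true_label = rep_len(label, n)
    ),
    flow_rate = 30, duration = duration
  )
}

# Ten identical bead events establishing bead_median_signal = 1 and phase
# baseline = `phase`.
unit_bead_calibration <- function(phase = 0) {
  calibrate_size(
    tibble::tibble(
      re_1mhz = rep(1, 10),
      re_500mhz = cos(rep(phase, 10)), im_500mhz = sin(rep(phase, 10))
    ),
    bead_diameter = 2
  )
}
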