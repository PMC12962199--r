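# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_phantom <- function() cached("phantom", make_phantom(phantom_params(), seed = 1L))

# noiseless, motion-free single-repetition series for the default phantom
noiseless_series <- function() cached("series0", {
  ph <- default_phantom()
  simulate_echo_series(ph$truth, ph$geometry, snr = Inf, motion_amplitude = 0,
                       n_reps = 1L, seed = 1L)
})

noisy_series <- function() cached("series20", {
  ph <- default_phantom()
  simulate_echo_series(ph$truth, ph$geometry, snr = 20, motion_amplitude = 0,
                       n_reps = 1L, seed = 2L)
})

# spatially uniform truth: every voxel is "lung" with the given parameters
uniform_truth <- function(n = 32L, m0 = 1, t2star_us = 640, nu_hz = 70,
                          phi0 = 0.2) {
  structure(list(
    m0_map = matrix(m0, n, n), t2star_map = matrix(t2star_us, n, n),
    nu_map = matrix(nu_hz, n, n), phi0_map = matrix(phi0, n, n),
    lung_mask = matrix(TRUE, n, n), body_mask = matrix(TRUE, n, n),
    deformations = list(array(0, dim = c(n, n, 2)))
  ), class = "phantom_truth")
}

small_geometry <- function(n = 32L) geometry2d(c(n, n), c(450, 450) * n / 128)

# Brute-force chi^2 grid minimizer over (nu, phi0) — the independent oracle
# for the field-map least squares. Hierarchical evaluation of the same
# quadratic cost on a dense grid: coarse pass over the full unambiguous range
# +/- 1/(2 dT), then a fine pass at 0.1 Hz x 1e-3 rad around the coarse
# minimum.
grid_chi2_min <- function(phases, dt_us) {
  t <- (seq_along(phases) - 1) * dt_us * 1e-6
  y <- phases
  chi2_grid <- function(nus, phis) {
    # chi2 = sum_j (y_j - 2 pi nu t_j - phi)^2, expanded in grid-separable form
    A <- 4 * pi^2 * sum(t^2)
    B <- length(y)
    C <- 4 * pi * sum(t)
    D <- -4 * pi * sum(t * y)
    E <- -2 * sum(y)
    F <- sum(y^2)
    outer(A * nus^2 + D * nus, B * phis^2 + E * phis, "+") +
      outer(C * nus, phis) + F
  }
  nu_lim <- 1 / (2 * dt_us * 1e-6)
  refine <- function(nus, phis) {
    g <- chi2_grid(nus, phis)
    k <- arrayInd(which.min(g), dim(g))
    c(nus[k[1]], phis[k[2]])
  }
  # the chi^2 valley is elongated (slope/intercept strongly correlated), so
  # each stage's window must cover the along-valley uncertainty of the
  # previous stage's cell size
  p <- refine(seq(-nu_lim, nu_lim, by = 2), seq(-pi, pi, by = 0.02))
  p <- refine(seq(p[1] - 30, p[1] + 30, by = 0.5),
              seq(p[2] - 0.06, p[2] + 0.06, by = 2e-3))
  # final stage finer than the asserted 0.1 Hz x 1e-3 rad resolution, so the
  # grid minimum stays within that tolerance even along the valley
  p <- refine(seq(p[1] - 2, p[1] + 2, by = 0.05),
              seq(p[2] - 0.008, p[2] + 0.008, by = 1e-4))
  c(nu = p[1], phi0 = p[2])
}

# fraction of voxels with positive Jacobian determinant of (id + u)
jacobian_positive_frac <- function(disp) {
  ur <- disp[, , 1]; uc <- disp[, , 2]
  d_r <- function(m) (m[c(seq_len(nrow(m) - 1) + 1, nrow(m)), ] -
                        m[c(1, seq_len(nrow(m) - 1)), ]) / 2
  d_c <- function(m) (m[, c(seq_len(ncol(m) - 1) + 1, ncol(m))] -
                        m[, c(1, seq_len(ncol(m) - 1))]) / 2
  jac <- (1 + d_r(ur)) * (1 + d_c(uc)) - d_c(ur) * d_r(uc)
  mean(jac > 0)
}
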