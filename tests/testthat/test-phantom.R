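test_that("default phantom hits the configured in-lung field statistics", {
  ph <- default_phantom()
  v <- ph$truth$nu_map[ph$truth$lung_mask]
  expect_lt(abs(mean(v) - 85), 1)           # requested mean within 1 Hz
  expect_lt(abs((max(v) - min(v)) - 434), 5) # requested range within 5 Hz
  # two lungs, inside the body, away from the border
  lab <- lungshim:::label_components(ph$truth$lung_mask)
  expect_identical(attr(lab, "n"), 2L)
  expect_true(all(ph$truth$body_mask[ph$truth$lung_mask]))
  m <- ph$truth$lung_mask
  expect_false(any(m[1, ] | m[nrow(m), ] | m[, 1] | m[, ncol(m)]))
  expect_true(all(ph$truth$t2star_map > 0))
  # lung T2* at the configured value, soft tissue slow-decaying
  expect_equal(unique(ph$truth$t2star_map[m]), 640)
  expect_gte(min(ph$truth$t2star_map[!m]), 10000)
})

test_that("zero field model yields an identically zero off-resonance map", {
  p <- phantom_params(background_amp_hz = 0, diaphragm_amp_hz = 0,
                      apex_amp_hz = 0)
  ph <- make_phantom(p, seed = 3)
  expect_true(all(ph$truth$nu_map == 0))
})

test_that("phantom generation is deterministic and validates its inputs", {
  expect_identical(make_phantom(phantom_params(), seed = 11),
                   make_phantom(phantom_params(), seed = 11))
  expect_error(make_phantom(phantom_params(matrix = c(16L, 16L))),
               "at least 32")
  expect_error(geometry2d(c(0, 128)), "invalid geometry")
  expect_error(geometry2d(c(128, 128), c(-450, 450)), "invalid geometry")
})

test_that("simulated signal follows the stated forward model", {
  # single voxel, frozen against direct evaluation of the decay/phase model
  tr <- uniform_truth(n = 32, m0 = 1, t2star_us = 640, nu_hz = 70, phi0 = 0.2)
  g <- small_geometry(32)
  s <- simulate_echo_series(tr, g, te1 = 570, delta_t = 100, n_echoes = 4,
                            n_reps = 1, snr = Inf, motion_amplitude = 0,
                            seed = 1)
  v <- s$data[16, 16, 1, 1]
  expect_equal(Mod(v), 0.41036, tolerance = 1e-4)
  expect_equal(Arg(v), 0.45069, tolerance = 1e-4)
  # TE list arithmetic as printed: 570, 670, 770, 870 us
  expect_identical(s$te_list, c(570, 670, 770, 870))
  expect_equal(s$te_list[4] - s$te_list[1], 3 * 100)
})

test_that("noiseless magnitude decays strictly and phase increments linearly", {
  s <- noiseless_series()
  ph <- default_phantom()
  vox <- which(ph$truth$lung_mask, arr.ind = TRUE)[100, ]
  mags <- Mod(s$data[vox[1], vox[2], , 1])
  expect_true(all(diff(mags) < 0))
  # phase of s_j / s_1 equals 2 pi nu (j-1) dT, phi0 cancels
  nu <- ph$truth$nu_map[vox[1], vox[2]]
  ratios <- s$data[vox[1], vox[2], , 1] / s$data[vox[1], vox[2], 1, 1]
  expect_equal(Arg(ratios), 2 * pi * nu * (0:3) * 100e-6, tolerance = 1e-10)
})

test_that("no noise and no motion gives bit-identical repetitions", {
  tr <- uniform_truth()
  s <- simulate_echo_series(tr, small_geometry(), snr = Inf,
                            motion_amplitude = 0, n_reps = 3, seed = 1)
  expect_identical(s$data[, , , 1], s$data[, , , 2])
  expect_identical(s$data[, , , 1], s$data[, , , 3])
})

test_that("empirical SNR matches the request within 10 percent", {
  ph <- default_phantom()
  s <- simulate_echo_series(ph$truth, ph$geometry, snr = 20,
                            motion_amplitude = 0, n_reps = 1, seed = 9)
  clean <- ph$truth$m0_map * exp(-570 / ph$truth$t2star_map)
  lung <- ph$truth$lung_mask
  noise_sd <- stats::sd(Mod(s$data[, , 1, 1])[lung] - clean[lung])
  snr_emp <- mean(clean[lung]) / noise_sd
  expect_lt(abs(snr_emp - 20) / 20, 0.10)
})

test_that("simulator rejects invalid acquisition requests", {
  tr <- uniform_truth()
  g <- small_geometry()
  expect_error(simulate_echo_series(tr, g, n_echoes = 1), "impossible")
  expect_error(simulate_echo_series(tr, g, te1 = 0), "positive")
  expect_error(simulate_echo_series(tr, g, snr = 0), "positive")
  expect_error(simulate_echo_series(tr, g, motion_amplitude = 1e5),
               "exceeds image extent")
})

test_that("phantom deformations are smooth, invertible, reference-anchored", {
  ph <- default_phantom()
  defs <- ph$truth$deformations
  expect_length(defs, 3)
  expect_true(all(defs[[1]] == 0))
  for (d in defs) {
    expect_true(all(is.finite(d)))
    expect_gte(jacobian_positive_frac(d), 0.99)
  }
  expect_equal(max(abs(defs[[2]][, , 1])),
               5 * abs(sin(2 * pi / 3)), tolerance = 0.15)
})
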