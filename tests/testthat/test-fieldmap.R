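test_that("incremental ratios self-normalize and track the decay model", {
  s <- noiseless_series()
  ph <- default_phantom()
  inc <- incremental_ratios(s)
  # echo 1 is identically 1 / phase 0 on valid voxels
  expect_true(all(inc$phase[, , 1][inc$valid] == 0))
  expect_true(all(Mod(inc$ratio[, , 1][inc$valid] - 1) < 1e-12))
  # |ratio_j| equals the magnitude decay ratio of the forward model
  vox <- which(ph$truth$lung_mask & inc$valid, arr.ind = TRUE)[50, ]
  t2 <- ph$truth$t2star_map[vox[1], vox[2]]
  expect_equal(Mod(inc$ratio[vox[1], vox[2], ]),
               exp(-(s$te_list - s$te_list[1]) / t2), tolerance = 1e-10)
  # identical echoes: all ratios 1, all phases 0
  s2 <- s
  for (j in 2:s$n_echoes) s2$data[, , j, 1] <- s2$data[, , 1, 1]
  inc2 <- incremental_ratios(s2)
  expect_true(all(abs(inc2$phase[, , ][!is.na(inc2$phase)]) < 1e-12))
})

test_that("fit recovers the printed 70 Hz example and null input", {
  phases <- array(c(0, 0.04398, 0.08796, 0.13195), dim = c(1, 1, 4))
  fm <- fit_fieldmap(phases, te_spacing = 100)
  expect_equal(fm$nu_hat[1, 1], 70, tolerance = 0.05)
  expect_equal(fm$phi0_hat[1, 1], 0, tolerance = 1e-3)
  z <- fit_fieldmap(array(0, dim = c(2, 2, 4)), 100)
  expect_true(all(z$nu_hat == 0) && all(z$phi0_hat == 0) &&
                all(z$residual_rms == 0))
})

test_that("two-echo fits force the intercept to zero and flag it", {
  phases <- array(c(0, 0.0440), dim = c(1, 1, 2))
  fm <- fit_fieldmap(phases, 100)
  expect_true(fm$phi0_forced_zero)
  expect_equal(fm$phi0_hat[1, 1], 0)
  expect_equal(fm$nu_hat[1, 1], 0.0440 / (2 * pi * 100e-6), tolerance = 1e-9)
})

test_that("least squares equals the brute-force chi-square grid minimum", {
  set.seed(42)
  for (k in 1:20) {
    nu <- runif(1, -1500, 1500)
    phi <- runif(1, -1, 1)
    y <- 2 * pi * nu * (0:3) * 100e-6 + phi + rnorm(4, sd = 0.05)
    y[1] <- 0   # first echo phase is identically zero after normalization
    fm <- fit_fieldmap(array(y, dim = c(1, 1, 4)), 100)
    oracle <- grid_chi2_min(unwrap_incremental_phases(y), 100)
    expect_lt(abs(fm$nu_hat[1, 1] - oracle["nu"]), 0.1)
    expect_lt(abs(fm$phi0_hat[1, 1] - oracle["phi0"]), 1e-3)
  }
})

test_that("noiseless phantom field is recovered exactly and wrap-free", {
  ph <- default_phantom()
  fm <- compute_fieldmap(noiseless_series())
  err <- abs(fm$nu_hat - ph$truth$nu_map)[fm$valid_mask]
  expect_lt(max(err), 1e-6)
  expect_false(any(fm$wrap_flag[fm$valid_mask]))
  # unambiguous range invariant
  expect_lt(max(abs(fm$nu_hat[fm$valid_mask])), 1 / (2 * 100e-6))
  # wrap-freedom holds up to |nu| = 2000 Hz at dT = 100 us
  tr <- uniform_truth(nu_hz = 2000)
  s <- simulate_echo_series(tr, small_geometry(), snr = Inf,
                            motion_amplitude = 0, n_reps = 1, seed = 1)
  fm2 <- compute_fieldmap(s)
  expect_false(any(fm2$wrap_flag[fm2$valid_mask]))
  expect_equal(fm2$nu_hat[5, 5], 2000, tolerance = 1e-6)
})

test_that("background voxels are excluded, not raised as errors", {
  ph <- default_phantom()
  fm <- compute_fieldmap(noiseless_series())
  outside <- !ph$truth$body_mask & !fm$valid_mask
  expect_gt(sum(outside), 0)
  expect_true(all(is.na(fm$nu_hat[!fm$valid_mask])))
  expect_error(fit_fieldmap(array(NA_real_, dim = c(4, 4, 4)), 100),
               "no valid voxels")
})

test_that("T2* estimation matches the printed value and a regression oracle", {
  te <- c(570, 670, 770, 870)
  mags <- exp(-te / 640)
  fit <- estimate_t2star(mags, te)
  expect_equal(fit$t2star_us, 640, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # constant magnitudes: no decay sentinel
  flat <- estimate_t2star(rep(0.5, 4), te)
  expect_identical(flat$t2star_us, Inf)
  expect_true(flat$no_decay_flag)
  expect_true(is.na(flat$r_squared))
  # noisy decay equals independent lm() fit of log magnitude
  set.seed(7)
  m <- exp(-te / 800) * exp(rnorm(4, sd = 0.02))
  fit2 <- estimate_t2star(m, te)
  lmfit <- stats::lm(log(m) ~ te)
  expect_equal(fit2$t2star_us, -1 / unname(stats::coef(lmfit)[2]),
               tolerance = 1e-9)
  expect_equal(fit2$r_squared, summary(lmfit)$r.squared, tolerance = 1e-9)
})

test_that("field-map precision scales inversely with SNR", {
  tr <- uniform_truth(n = 32)
  g <- small_geometry(32)
  sds <- vapply(c(10, 20, 40), function(snr) {
    s <- simulate_echo_series(tr, g, snr = snr, motion_amplitude = 0,
                              n_reps = 1, seed = 31)
    fm <- compute_fieldmap(s)
    stats::sd(fm$nu_hat[fm$valid_mask])
  }, numeric(1))
  expect_lt(abs(sds[1] / sds[2] - 2) / 2, 0.15)
  expect_lt(abs(sds[2] / sds[3] - 2) / 2, 0.15)
  # reported per-voxel precision agrees with the Monte-Carlo spread
  s <- simulate_echo_series(tr, g, snr = 20, motion_amplitude = 0,
                            n_reps = 1, seed = 32)
  fm <- compute_fieldmap(s)
  expect_lt(abs(stats::median(fm$precision_hz[fm$valid_mask]) - sds[2]) / sds[2],
            0.5)
})
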