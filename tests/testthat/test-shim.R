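test_that("basis matches the printed harmonic functions", {
  g <- geometry2d(c(128, 128), c(450, 450))
  basis <- build_basis(g, order = 2)
  expect_identical(ncol(basis$A), 9L)
  expect_identical(basis$excluded, c(3L, 6L, 8L))
  # y-dependent columns vanish identically under the y = 0 convention
  expect_true(all(basis$A[, 4] == 0))
  expect_true(all(basis$A[, 7] == 0))
  expect_true(all(basis$A[, 9] == 0))
  expect_true(all(basis$A[, 1] == 1))
  # direct evaluation at printed coordinates
  expect_equal(drop(shim_basis_at(x = 0, z = 0)),
               c(1, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(drop(shim_basis_at(x = 100, z = 200)),
               c(1, 200, 100, 0, 35000, 20000, 0, 10000, 0))
  # basis columns agree with pointwise evaluation on the grid
  grids <- lungshim:::coordinate_grids(g)
  i <- 1000
  expect_equal(basis$A[i, ],
               drop(shim_basis_at(as.numeric(grids$x)[i], as.numeric(grids$z)[i])),
               ignore_attr = TRUE)
  expect_identical(ncol(build_basis(g, order = 1)$A), 4L)
  expect_identical(ncol(build_basis(g, order = 0)$A), 1L)
})

make_const_field <- function(nu, geometry) {
  structure(list(nu_hat = nu, phi0_hat = nu * 0, residual_rms = nu * 0,
                 precision_hz = nu * 0, valid_mask = is.finite(nu),
                 wrap_flag = nu * 0 > 1, phi0_forced_zero = FALSE,
                 geometry = geometry), class = "field_map")
}

test_that("constant field maps entirely onto the frequency term", {
  ph <- default_phantom()
  basis <- build_basis(ph$geometry)
  fld <- make_const_field(matrix(100, 128, 128), ph$geometry)
  sol <- solve_shim(fld, ph$truth$lung_mask, basis)
  expect_equal(unname(sol$coefficients[1]), 100, tolerance = 1e-9)
  expect_lt(max(abs(sol$coefficients[-1])), 1e-9)
})

test_that("forward-constructed harmonic fields are recovered exactly", {
  ph <- default_phantom()
  basis <- build_basis(ph$geometry)
  c_true <- c(40, 0.5, -0.3, 0, 2e-3, -1e-3, 0, 5e-4, 0)
  nu <- matrix(drop(basis$A %*% c_true), 128, 128)
  fld <- make_const_field(nu, ph$geometry)
  sol <- solve_shim(fld, ph$truth$lung_mask, basis)
  nz <- c_true != 0
  expect_lt(max(abs(sol$coefficients[nz] - c_true[nz]) / abs(c_true[nz])), 1e-9)
  expect_lt(sqrt(sol$residual_ss / sol$n_voxels), 1e-9)
  res <- predict_residual(fld, sol, basis)
  expect_lt(max(abs(res$nu_hat[ph$truth$lung_mask])), 1e-9)
})

test_that("solution equals the normal equations on a random 50-voxel mask", {
  set.seed(12)
  g <- geometry2d(c(40, 40), c(300, 300))
  basis <- build_basis(g)
  nu <- matrix(rnorm(1600, sd = 50), 40, 40)
  mask <- matrix(FALSE, 40, 40)
  mask[sample(1600, 50)] <- TRUE
  fld <- make_const_field(nu, g)
  sol <- solve_shim(fld, mask, basis)
  keep <- c(1, 2, 3, 5, 6, 8)
  A <- basis$A[as.logical(mask), keep]
  ref <- solve(crossprod(A), crossprod(A, nu[mask]))   # independent oracle
  expect_equal(unname(sol$coefficients[keep]), unname(drop(ref)),
               tolerance = 1e-6)
})

test_that("excluded coefficients are exactly zero for any input", {
  ph <- default_phantom()
  basis <- build_basis(ph$geometry)
  set.seed(3)
  for (k in 1:5) {
    nu <- matrix(rnorm(128 * 128, sd = 100), 128, 128)
    sol <- solve_shim(make_const_field(nu, ph$geometry),
                      ph$truth$lung_mask, basis)
    expect_identical(unname(sol$coefficients[c(4, 7, 9)]), c(0, 0, 0))
  }
})

test_that("degenerate masks are rejected with named directions", {
  g <- geometry2d(c(40, 40), c(300, 300))
  basis <- build_basis(g)
  nu <- matrix(rnorm(1600), 40, 40)
  fld <- make_const_field(nu, g)
  line <- matrix(FALSE, 40, 40); line[20, ] <- TRUE   # z constant on a row
  expect_error(solve_shim(fld, line, basis), "rank-deficient")
  empty <- matrix(FALSE, 40, 40)
  expect_error(solve_shim(fld, empty, basis), "empty mask")
  tiny <- matrix(FALSE, 40, 40); tiny[cbind(1:3, 1:3)] <- TRUE
  expect_error(solve_shim(fld, tiny, basis), "too few")
})

test_that("zero solution leaves the field untouched; LSQ always improves", {
  ph <- default_phantom()
  basis <- build_basis(ph$geometry)
  fm <- compute_fieldmap(noiseless_series())
  zero <- structure(list(coefficients = stats::setNames(numeric(9),
                                                        lungshim:::SHIM_TERMS),
                         excluded = c(3L, 6L, 8L)), class = "shim_solution")
  expect_identical(predict_residual(fm, zero, basis)$nu_hat, fm$nu_hat)
  sol <- solve_shim(fm, ph$truth$lung_mask, basis)
  expect_lte(sol$residual_ss, sol$pre_ss)
  res <- predict_residual(fm, sol, basis)
  sel <- ph$truth$lung_mask & fm$valid_mask
  expect_lte(mean(abs(res$nu_hat[sel])), mean(abs(fm$nu_hat[sel])))
})

test_that("excluding the y-columns is equivalent to the full min-norm fit", {
  # the y-dependent columns are identically zero at y = 0, so the minimum-norm
  # least squares over all nine columns (SVD pseudoinverse oracle) must agree
  # with the solver's exclusion approach on every retained coefficient
  ph <- default_phantom()
  basis <- build_basis(ph$geometry)
  fm <- compute_fieldmap(noiseless_series())
  sol <- solve_shim(fm, ph$truth$lung_mask, basis)
  sel <- ph$truth$lung_mask & fm$valid_mask
  A <- basis$A[as.logical(sel), ]
  sc <- apply(abs(A), 2, max)
  sc[sc == 0] <- 1
  sv <- svd(sweep(A, 2, sc, "/"))
  dinv <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
  c_pinv <- drop(sv$v %*% (dinv * crossprod(sv$u, fm$nu_hat[sel]))) / sc
  expect_equal(unname(sol$coefficients), unname(c_pinv), tolerance = 1e-8)
})

test_that("shim config files round-trip and validate", {
  sol <- structure(list(coefficients = stats::setNames(
    c(11.123456, 0.5, -0.25, 0, 1.5e-3, -2e-3, 0, 7.77e-4, 0),
    lungshim:::SHIM_TERMS), excluded = c(3L, 6L, 8L),
    residual_ss = 1, pre_ss = 2, condition_number = 3, n_voxels = 10L),
    class = "shim_solution")
  path <- withr::local_tempfile(fileext = ".txt")
  g <- geometry2d(c(128, 128), c(450, 450))
  write_shim_config(sol, path, g)
  back <- read_shim_config(path)
  keep <- c(1, 2, 3, 5, 6, 8)
  expect_equal(unname(back$coefficients[keep]),
               unname(round(sol$coefficients[keep], 6)), tolerance = 1e-12)
  expect_identical(unname(back$coefficients[c(4, 7, 9)]), c(0, 0, 0))
  expect_equal(back$geometry$matrix, g$matrix, ignore_attr = TRUE)
  # second round trip is bit-stable
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_shim_config(back, path2, back$geometry)
  expect_identical(grep("^c", readLines(path), value = TRUE),
                   grep("^c", readLines(path2), value = TRUE))

  # missing key named in the error
  lines <- readLines(path)
  writeLines(lines[!grepl("f0_offset_hz", lines)], path)
  expect_error(read_shim_config(path), "f0_offset_hz")
  writeLines(c("f0_offset_hz = 1.0", "junk line without equals sign",
               "c1_z_hz_per_mm = oops = 3"), path)
  expect_error(read_shim_config(path), "malformed")
})

test_that("hand-written config maps directly onto coefficients", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("f0_offset_hz = 11.0", "c1_z_hz_per_mm = 0.25",
               "c2_x_hz_per_mm = -0.5", "c4_z2_hz_per_mm2 = 0.001",
               "c5_zx_hz_per_mm2 = 0", "c7_x2y2_hz_per_mm2 = -0.002"), path)
  sol <- adjust_shim(path)
  expect_identical(unname(sol$coefficients[1]), 11.0)
  expect_identical(unname(sol$coefficients[2]), 0.25)
  expect_identical(unname(sol$coefficients[8]), -0.002)
})
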