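# Synthetic coronal thorax phantom and TR-shifted multi-echo GRE simulator.
# The phantom is the test bed for every downstream stage: it carries the
# ground-truth off-resonance, T2*, proton density, lung mask and the
# per-repetition respiratory deformations.

#' Phantom configuration
#'
#' Defaults encode the conditions the method was designed for: a 128 x 128
#' coronal slice with a 450 x 450 mm FOV, lung T2* of 640 us, and an in-lung
#' off-resonance distribution with mean 85 Hz and max-min range 434 Hz,
#' built from a low-order harmonic background plus a negative perturbation at
#' the diaphragm and a positive one near the lung apex.
#'
#' @param matrix image matrix size `c(rows, cols)`.
#' @param fov_mm field of view `c(fov_z, fov_x)` in mm.
#' @param target_mean_hz requested in-lung mean off-resonance (Hz); `NA`
#'   disables rescaling.
#' @param target_range_hz requested in-lung max-min range (Hz).
#' @param background_amp_hz amplitude of the low-order harmonic background.
#' @param diaphragm_amp_hz amplitude of the negative diaphragm perturbation.
#' @param apex_amp_hz amplitude of the positive apical perturbation.
#' @param lung_t2star_us,tissue_t2star_us T2* (us) inside lung / soft tissue.
#' @param lung_m0,tissue_m0 proton-density scale inside lung / soft tissue.
#' @param n_reps number of respiratory repetitions to generate deformations
#'   for (repetition 1 is the motion reference).
#' @param motion_amplitude_px peak head-foot diaphragm displacement (pixels).
#' @param motion_residual_frac amplitude of the random smooth residual motion,
#'   as a fraction of `motion_amplitude_px`.
#' @return a list of class `phantom_params`.
#' @export
phantom_params <- function(matrix = c(128L, 128L), fov_mm = c(450, 450),
                           target_mean_hz = 85, target_range_hz = 434,
                           background_amp_hz = 60, diaphragm_amp_hz = 150,
                           apex_amp_hz = 180,
                           lung_t2star_us = 640, tissue_t2star_us = 20000,
                           lung_m0 = 0.25, tissue_m0 = 1,
                           n_reps = 3L, motion_amplitude_px = 5,
                           motion_residual_frac = 0.1) {
  structure(as.list(environment()), class = "phantom_params")
}

#' Generate a ground-truth thorax phantom
#'
#' Builds the body ellipse with two lung regions, the true off-resonance map
#' (harmonic background, negative diaphragm blob, positive apical blob,
#' affinely rescaled so the in-lung mean and max-min range hit the configured
#' targets), T2* and proton-density maps, a smooth phase-offset map, and one
#' smooth deformation field per repetition (repetition 1 is identity).
#'
#' @param params a [phantom_params()] list.
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return list with elements `truth` (class `phantom_truth`: `m0_map`,
#'   `t2star_map` (us), `nu_map` (Hz), `phi0_map` (rad), `lung_mask`,
#'   `body_mask`, `deformations`) and `geometry` ([geometry2d()]).
#' @export
make_phantom <- function(params = phantom_params(), seed = 1L) {
  p <- params
  if (any(p$matrix < 32)) {
    stop("invalid geometry: phantom matrix must be at least 32", call. = FALSE)
  }
  geometry <- geometry2d(p$matrix, p$fov_mm)
  g <- coordinate_grids(geometry)
  x <- g$x; z <- g$z
  Lz <- geometry$fov_mm[1] / 2; Lx <- geometry$fov_mm[2] / 2

  # anatomy: body ellipse and two lungs (ellipses clipped by a diaphragm dome)
  body <- (x / (0.80 * Lx))^2 + (z / (0.92 * Lz))^2 <= 1
  lung_cx <- 0.33 * Lx
  lung_cz <- 0.10 * Lz
  lung_sx <- 0.21 * Lx
  lung_sz <- 0.44 * Lz
  dome <- function(xc) {
    -0.36 * Lz + 0.14 * Lz * exp(-((x - xc) / (0.22 * Lx))^2)
  }
  right <- ((x + lung_cx) / lung_sx)^2 + ((z - lung_cz) / lung_sz)^2 <= 1 &
    z > dome(-lung_cx)
  left <- ((x - lung_cx) / lung_sx)^2 + ((z - lung_cz) / lung_sz)^2 <= 1 &
    z > dome(lung_cx)
  lung <- (right | left) & body

  m0 <- matrix(0, nrow(x), ncol(x))
  m0[body] <- p$tissue_m0
  m0[lung] <- p$lung_m0
  m0 <- smooth_gaussian(m0, 0.7)  # soften edges for realistic gradients
  t2 <- matrix(p$tissue_t2star_us, nrow(x), ncol(x))
  t2[lung] <- p$lung_t2star_us

  # off-resonance: harmonic background + diaphragm / apex perturbations
  nu_raw <- p$background_amp_hz *
    (0.5 * (z / Lz) + 0.3 * (x / Lx) + 0.4 * ((z / Lz)^2 - 0.5 * (x / Lx)^2))
  dia_z <- -0.30 * Lz
  apex_z <- lung_cz + 0.95 * lung_sz
  for (s in c(-1, 1)) {
    nu_raw <- nu_raw - p$diaphragm_amp_hz *
      exp(-(((x - s * lung_cx) / (0.18 * Lx))^2 + ((z - dia_z) / (0.14 * Lz))^2))
    nu_raw <- nu_raw + p$apex_amp_hz *
      exp(-(((x - s * lung_cx) / (0.16 * Lx))^2 + ((z - apex_z) / (0.12 * Lz))^2))
  }

  in_lung <- nu_raw[lung]
  raw_range <- max(in_lung) - min(in_lung)
  nu <- nu_raw
  zero_model <- p$background_amp_hz == 0 && p$diaphragm_amp_hz == 0 &&
    p$apex_amp_hz == 0
  if (!zero_model && !is.na(p$target_mean_hz) && !is.na(p$target_range_hz)) {
    if (raw_range <= 0) {
      stop("configuration error: requested in-lung range is infeasible for a ",
           "constant raw field", call. = FALSE)
    }
    b <- p$target_range_hz / raw_range
    a <- p$target_mean_hz - b * mean(in_lung)
    nu <- a + b * nu_raw
  }

  phi0 <- 0.2 + 0.3 * (x / Lx) - 0.2 * (z / Lz)

  deformations <- make_deformations(geometry, n_reps = p$n_reps,
                                    amplitude_px = p$motion_amplitude_px,
                                    residual_frac = p$motion_residual_frac,
                                    seed = seed)

  truth <- structure(list(
    m0_map = m0, t2star_map = t2, nu_map = nu, phi0_map = phi0,
    lung_mask = lung, body_mask = body, deformations = deformations
  ), class = "phantom_truth")
  list(truth = truth, geometry = geometry)
}

# Per-repetition respiratory deformation fields: diaphragm-dominant head-foot
# displacement (sinusoidal over the repetition index) weighted towards the
# lower thorax, plus a small random smooth residual. Repetition 1 is identity.
make_deformations <- function(geometry, n_reps, amplitude_px, residual_frac,
                              seed) {
  g <- coordinate_grids(geometry)
  Lz <- geometry$fov_mm[1] / 2; Lx <- geometry$fov_mm[2] / 2
  w <- 1 / (1 + exp((g$z - (-0.18 * Lz)) / (0.13 * Lz))) *
    exp(-(g$x / (0.85 * Lx))^2)
  nr <- geometry$matrix[1]; nc <- geometry$matrix[2]
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_reps), function(r) {
      d <- array(0, dim = c(nr, nc, 2))
      if (r > 1) {
        a <- amplitude_px * sin(2 * pi * (r - 1) / n_reps)
        d[, , 1] <- a * w
        res <- residual_frac * amplitude_px
        if (res > 0) {
          for (k in 1:2) {
            f <- smooth_gaussian(matrix(stats::rnorm(nr * nc), nr, nc), 6)
            f <- f / max(abs(f)) * res
            d[, , k] <- d[, , k] + f * w
          }
        }
      }
      d
    })
  })
}

#' Simulate a TR-shifted multi-echo gradient-echo series
#'
#' Per voxel and echo j, the noiseless complex signal is
#' `M0 * exp(-TEj / T2*) * exp(i * (2 pi nu TEj + phi0))` with
#' `TEj = (j - 1) * delta_t + te1`. Each repetition is warped by the phantom's
#' respiratory deformation (scaled to `motion_amplitude`) before sampling, and
#' complex Gaussian noise with per-channel standard deviation
#' (mean in-lung first-echo magnitude) / snr is added.
#'
#' @param truth a `phantom_truth` object from [make_phantom()].
#' @param geometry the matching [geometry2d()].
#' @param te1 first echo time (us).
#' @param delta_t inter-echo spacing (us).
#' @param n_echoes number of echo-shifted images (>= 2).
#' @param n_reps number of repetitions to simulate.
#' @param snr signal-to-noise ratio of the in-lung first-echo magnitude;
#'   `Inf` for noiseless data.
#' @param motion_amplitude peak diaphragm displacement in pixels; 0 disables
#'   motion. The phantom's stored deformations are rescaled to this value.
#' @param seed integer seed for the noise.
#' @return an `echo_series`: list with `data` (complex array
#'   `[rows, cols, echo, rep]`), `te_list` (us), `delta_t` (us), `geometry`.
#' @export
simulate_echo_series <- function(truth, geometry, te1 = 570, delta_t = 100,
                                 n_echoes = 4L, n_reps = 3L, snr = Inf,
                                 motion_amplitude = NULL, seed = 1L) {
  if (te1 <= 0 || delta_t <= 0) stop("te1 and delta_t must be positive", call. = FALSE)
  if (n_echoes < 2) stop("n_echoes must be >= 2: field mapping impossible", call. = FALSE)
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  if (is.null(motion_amplitude)) {
    motion_amplitude <- max(vapply(truth$deformations,
                                   function(d) max(abs(d)), numeric(1)))
  }
  if (motion_amplitude > min(geometry$matrix)) {
    stop("motion amplitude exceeds image extent", call. = FALSE)
  }
  nr <- geometry$matrix[1]; nc <- geometry$matrix[2]
  te_list <- te1 + (seq_len(n_echoes) - 1) * delta_t

  base_amp <- max(vapply(truth$deformations, function(d) max(abs(d)),
                         numeric(1)))
  scale <- if (base_amp > 0 && motion_amplitude > 0) {
    motion_amplitude / base_amp
  } else 0

  if (scale > 0 && n_reps > length(truth$deformations)) {
    stop("phantom provides deformations for ", length(truth$deformations),
         " repetitions; requested ", n_reps, call. = FALSE)
  }

  sigma <- if (is.finite(snr)) {
    mag1 <- truth$m0_map * exp(-te1 / truth$t2star_map)
    mean(mag1[truth$lung_mask]) / snr
  } else 0

  data <- array(complex(real = 0), dim = c(nr, nc, n_echoes, n_reps))
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_reps)) {
      if (scale > 0) {
        d <- truth$deformations[[min(r, length(truth$deformations))]] * scale
        m0 <- warp_matrix(truth$m0_map, d)
        t2 <- warp_matrix(truth$t2star_map, d)
        nu <- warp_matrix(truth$nu_map, d)
        ph <- warp_matrix(truth$phi0_map, d)
      } else {
        m0 <- truth$m0_map; t2 <- truth$t2star_map
        nu <- truth$nu_map; ph <- truth$phi0_map
      }
      for (j in seq_len(n_echoes)) {
        te <- te_list[j]
        s <- m0 * exp(-te / t2) *
          exp(1i * (2 * pi * nu * te * 1e-6 + ph))
        if (sigma > 0) {
          s <- s + complex(real = stats::rnorm(nr * nc, sd = sigma),
                           imaginary = stats::rnorm(nr * nc, sd = sigma))
        }
        data[, , j, r] <- s
      }
    }
  })
  echo_series(data, te_list, delta_t, geometry)
}

#' Construct an echo series container
#'
#' @param data complex array `[rows, cols, echo, rep]`.
#' @param te_list echo times (us), strictly increasing with constant spacing.
#' @param delta_t inter-echo spacing (us).
#' @param geometry a [geometry2d()].
#' @return object of class `echo_series`.
#' @export
echo_series <- function(data, te_list, delta_t, geometry) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4)
  n_echoes <- dim(data)[3]
  if (n_echoes < 2) stop("echo series needs at least 2 echoes", call. = FALSE)
  if (length(te_list) != n_echoes) {
    stop("te_list length must match the echo dimension", call. = FALSE)
  }
  d <- diff(te_list)
  if (any(d <= 0) || any(abs(d - delta_t) > 1e-9 * delta_t)) {
    stop("te_list must increase in constant steps of delta_t", call. = FALSE)
  }
  structure(list(data = data, te_list = te_list, delta_t = delta_t,
                 geometry = geometry,
                 n_echoes = n_echoes, n_reps = dim(data)[4]),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  cat(sprintf("<echo_series> %d x %d, %d echoes (TE %s us), %d repetition(s)\n",
              dim(x$data)[1], dim(x$data)[2], x$n_echoes,
              paste(x$te_list, collapse = ", "), x$n_reps))
  invisible(x)
}
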