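# Shim-benefit evaluation: in-mask field statistics/histograms and the
# balanced steady-state free precession (bSSFP) off-resonance response, whose
# signal nulls ("bands") sit at off-resonance frequencies +/- n / (2 TR) for
# odd n.

#' bSSFP sequence parameters
#'
#' Defaults follow the ultra-fast functional lung protocol (TR 1.38 ms,
#' TE 0.6 ms, flip 25 degrees) with representative 3T lung relaxation times
#' (T1 1300 ms, T2 40 ms) and 180-degree phase cycling.
#'
#' @param tr repetition time (ms).
#' @param te echo time (ms), `0 < te < tr`.
#' @param flip_angle flip angle (degrees), in (0, 180).
#' @param t1,t2 relaxation times (ms), `t2 <= t1`.
#' @param phase_cycling RF phase increment (degrees).
#' @return list of class `bssfp_params`.
#' @export
bssfp_params <- function(tr = 1.38, te = 0.6, flip_angle = 25,
                         t1 = 1300, t2 = 40, phase_cycling = 180) {
  if (tr <= 0 || te <= 0 || te >= tr) stop("need 0 < te < tr", call. = FALSE)
  if (flip_angle <= 0 || flip_angle >= 180) stop("flip_angle must be in (0, 180)", call. = FALSE)
  if (t2 > t1) stop("t2 must not exceed t1", call. = FALSE)
  structure(as.list(environment()), class = "bssfp_params")
}

#' In-mask field statistics and histogram
#'
#' @param field a `field_map` (or plain numeric matrix of Hz values).
#' @param mask a `lung_mask` or logical matrix.
#' @param bins number of histogram bins.
#' @return list with `mean_hz`, `range_hz` (max - min), `std_hz`, `min_hz`,
#'   `max_hz`, `n_voxels`, `histogram` (counts + break edges).
#' @export
mask_stats <- function(field, mask, bins = 50L) {
  nu <- if (inherits(field, "field_map")) field$nu_hat else field
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask > 0
  sel <- m & is.finite(nu)
  if (inherits(field, "field_map")) sel <- sel & field$valid_mask
  v <- nu[sel]
  if (length(v) == 0) stop("no valid in-mask voxels", call. = FALSE)
  h <- graphics::hist(v, breaks = bins, plot = FALSE)
  list(mean_hz = mean(v), range_hz = max(v) - min(v), std_hz = stats::sd(v),
       min_hz = min(v), max_hz = max(v), n_voxels = length(v),
       histogram = list(counts = h$counts, breaks = h$breaks))
}

#' bSSFP banding frequencies
#'
#' The signal nulls of balanced SSFP occur at off-resonance frequencies
#' `+/- n / (2 TR)` for odd integers n.
#'
#' @param params a [bssfp_params()] list.
#' @param n_max largest odd order to include.
#' @return numeric vector of banding frequencies (Hz), symmetric about 0,
#'   sorted ascending.
#' @export
band_frequencies <- function(params, n_max = 1L) {
  if (params$tr <= 0) stop("tr must be positive", call. = FALSE)
  n <- seq(1, n_max, by = 2)
  f <- n / (2 * params$tr * 1e-3)
  sort(c(-f, f))
}

#' Steady-state bSSFP signal magnitude at a given off-resonance
#'
#' Standard steady-state expression with `E1 = exp(-TR/T1)`,
#' `E2 = exp(-TR/T2)` and per-TR precession angle
#' `theta = 2 pi nu TR + phase_cycling`:
#' `|M| = |(1 - E1) sin(a) (1 - E2 e^{i theta})| /
#'   |(1 - E1 cos a)(1 - E2 cos theta) - E2 (E1 - cos a)(E2 - cos theta)|`.
#' Periodic in `nu` with period `1/TR`; with 180-degree cycling the pass-band
#' is centered on resonance and the bands sit at `+/- 1/(2 TR)`.
#'
#' @param params a [bssfp_params()] list.
#' @param nu off-resonance (Hz), vectorized.
#' @param m0 equilibrium magnetization scale.
#' @return signal magnitude (a.u.), same shape as `nu`.
#' @export
bssfp_profile <- function(params, nu, m0 = 1) {
  tr_s <- params$tr * 1e-3
  e1 <- exp(-params$tr / params$t1)
  e2 <- exp(-params$tr / params$t2)
  a <- params$flip_angle * pi / 180
  theta <- 2 * pi * nu * tr_s + params$phase_cycling * pi / 180
  num <- Mod(m0 * (1 - e1) * sin(a) * (1 - e2 * exp(1i * theta)))
  den <- abs((1 - e1 * cos(a)) * (1 - e2 * cos(theta)) -
               e2 * (e1 - cos(a)) * (e2 - cos(theta)))
  num / den
}

#' Render a bSSFP image from a field map and proton-density map
#'
#' Per-voxel magnitude `m0 * bssfp_profile(nu)`; optionally returns the
#' intensity histogram over a mask (the quantity that narrows and shifts to
#' higher values after successful shimming).
#'
#' @param field a `field_map` or numeric matrix of off-resonance (Hz).
#' @param m0 proton-density scale map (matrix).
#' @param params a [bssfp_params()] list.
#' @param mask optional `lung_mask` or logical matrix for the histogram.
#' @param bins histogram bins.
#' @return list with `image` (matrix) and, if `mask` given, `stats`
#'   (mean/std/histogram of in-mask intensities).
#' @export
render_bssfp <- function(field, m0, params = bssfp_params(), mask = NULL,
                         bins = 50L) {
  nu <- if (inherits(field, "field_map")) field$nu_hat else field
  if (!all(dim(nu) == dim(m0))) {
    stop("geometry mismatch between field and m0 map", call. = FALSE)
  }
  nu0 <- nu
  nu0[!is.finite(nu0)] <- 0
  img <- m0 * bssfp_profile(params, nu0)
  out <- list(image = img)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "lung_mask")) mask$mask else mask > 0
    v <- img[m & is.finite(nu)]
    h <- graphics::hist(v, breaks = bins, plot = FALSE)
    out$stats <- list(mean = mean(v), std = stats::sd(v), n_voxels = length(v),
                      histogram = list(counts = h$counts, breaks = h$breaks))
  }
  out
}
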