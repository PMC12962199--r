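# Voxel-wise off-resonance estimation from the incremental phase of a
# TR-shifted echo series, plus T2* estimation from the log-magnitude decay.
#
# The echo phases are first normalized to the first echo, s_j / s_1, whose
# principal argument evolves as 2 pi nu (j - 1) dT + phi0. With sub-
# millisecond echo spacing these incremental phases stay well inside
# (-pi, pi] for any physiologically plausible off-resonance, so no phase
# unwrapping is required; a guard flags voxels whose consecutive increments
# approach pi.

#' Incremental complex ratios and phases of an echo series
#'
#' Computes `ratio[j] = s_j / s_1` per voxel and its principal argument.
#' Voxels whose first-echo magnitude falls below `floor_frac` times the 99th
#' percentile of the first-echo magnitude are marked invalid (air background),
#' not raised as errors.
#'
#' @param series an `echo_series` with a single repetition (already averaged).
#' @param floor_frac background magnitude floor as a fraction of the in-image
#'   99th percentile (default 0.05).
#' @return list with `ratio` (complex array `[rows, cols, echo]`), `phase`
#'   (same shape, rad, principal values, identically 0 for echo 1), and
#'   `valid` (logical matrix).
#' @export
incremental_ratios <- function(series, floor_frac = 0.05) {
  stopifnot(inherits(series, "echo_series"))
  if (series$n_reps != 1) {
    stop("incremental_ratios expects a single repetition; run align_and_average first",
         call. = FALSE)
  }
  d <- series$data
  nr <- dim(d)[1]; nc <- dim(d)[2]; nj <- dim(d)[3]
  s1 <- d[, , 1, 1]
  m1 <- Mod(s1)
  floor_val <- floor_frac * stats::quantile(m1, 0.99, names = FALSE)
  valid <- m1 > floor_val & m1 > 0
  ratio <- array(complex(real = NA_real_), dim = c(nr, nc, nj))
  phase <- array(NA_real_, dim = c(nr, nc, nj))
  ratio[, , 1] <- ifelse(valid, complex(real = 1), NA_complex_)
  phase[, , 1] <- ifelse(valid, 0, NA_real_)
  for (j in seq_len(nj)[-1]) {
    rj <- d[, , j, 1] / s1
    rj[!valid] <- NA_complex_
    ratio[, , j] <- rj
    phase[, , j] <- Arg(rj)
  }
  list(ratio = ratio, phase = phase, valid = valid)
}

#' Temporal unwrapping of an incremental phase sequence
#'
#' The principal-valued cumulative phases `arg(s_j / s_1)` wrap once
#' `|2 pi nu (j - 1) dT|` exceeds pi, even though every per-step increment
#' stays inside (-pi, pi] for `|nu| < 1/(2 dT)`. This maps each consecutive
#' increment back to its principal value and re-accumulates, which
#' reconstructs the unwrapped sequence exactly whenever the per-step
#' increments are unambiguous. It is the phase sequence the field-map cost
#' function is evaluated on.
#'
#' @param phases numeric vector (one voxel) or array `[rows, cols, echo]`.
#' @return same shape, unwrapped, anchored at the first-echo phase.
#' @export
unwrap_incremental_phases <- function(phases) {
  if (is.null(dim(phases))) {
    d <- diff(phases)
    d <- d - 2 * pi * round(d / (2 * pi))
    return(phases[1] + c(0, cumsum(d)))
  }
  nj <- dim(phases)[3]
  Y <- matrix(phases, ncol = nj)
  D <- Y[, -1, drop = FALSE] - Y[, -nj, drop = FALSE]
  D <- D - 2 * pi * round(D / (2 * pi))
  cum <- if (nj == 2) D else t(apply(D, 1, cumsum))
  out <- cbind(Y[, 1], Y[, 1] + cum)
  array(out, dim = dim(phases))
}

#' Fit the off-resonance field map from incremental phases
#'
#' Per-voxel linear least squares of the incremental phase against elapsed
#' echo time `(j - 1) * dT`: the slope gives the local off-resonance `nu`
#' (Hz) and the intercept the phase offset `phi0` (rad). The phase sequence
#' is first unwrapped per step ([unwrap_incremental_phases()]); no spatial
#' unwrapping is ever needed. The first-echo phase (identically zero after
#' normalization) participates in the fit; the intercept absorbs first-echo
#' noise. With only two echoes the intercept is underdetermined and is
#' forced to zero (flagged in the output).
#'
#' @param phases numeric array `[rows, cols, echo]` of incremental phases
#'   (rad), echo 1 first; `NA` marks invalid voxels.
#' @param te_spacing inter-echo spacing dT (us).
#' @param weights optional array of per-echo, per-voxel weights (e.g. echo
#'   magnitudes); default unweighted.
#' @param geometry optional [geometry2d()] carried into the output.
#' @return object of class `field_map`: `nu_hat` (Hz), `phi0_hat` (rad),
#'   `residual_rms` (rad), `precision_hz` (frequency standard error, Hz),
#'   `valid_mask`, `wrap_flag` (voxels whose consecutive increments exceed
#'   0.9 pi), `phi0_forced_zero`, `geometry`.
#' @export
fit_fieldmap <- function(phases, te_spacing, weights = NULL, geometry = NULL) {
  stopifnot(length(dim(phases)) == 3)
  nr <- dim(phases)[1]; nc <- dim(phases)[2]; nj <- dim(phases)[3]
  if (nj < 2) stop("at least two echoes are required", call. = FALSE)
  valid <- !is.na(phases[, , 1])
  for (j in seq_len(nj)) valid <- valid & is.finite(phases[, , j])
  if (!any(valid)) stop("no valid voxels to fit", call. = FALSE)

  Y <- matrix(phases, nr * nc, nj)[valid, , drop = FALSE]   # voxels x echoes
  t_s <- (seq_len(nj) - 1) * te_spacing * 1e-6              # seconds

  # guard: per-step increments close to +/- pi are ambiguous
  dphi <- Y[, -1, drop = FALSE] - Y[, -nj, drop = FALSE]
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
  wrap <- apply(abs(dphi) > 0.9 * pi, 1, any)
  cum <- if (nj == 2) dphi else t(apply(dphi, 1, cumsum))
  Y <- cbind(Y[, 1], Y[, 1] + cum)

  W <- if (is.null(weights)) {
    matrix(1, sum(valid), nj)
  } else {
    matrix(weights, nr * nc, nj)[valid, , drop = FALSE]
  }

  phi0_forced_zero <- nj == 2
  if (phi0_forced_zero) {
    # through-origin fit: slope only (phi_1 = 0 by construction)
    slope <- (W[, 2] * Y[, 2] * t_s[2]) / (W[, 2] * t_s[2]^2)
    intercept <- rep(0, length(slope))
    res <- Y - outer(slope, t_s)
    rss <- rowSums(W * res^2)
    sigma2 <- rep(NA_real_, length(slope))  # no residual dof
    var_slope <- rep(NA_real_, length(slope))
  } else {
    Tm <- matrix(t_s, nrow(Y), nj, byrow = TRUE)
    sw <- rowSums(W)
    swt <- rowSums(W * Tm)
    swt2 <- rowSums(W * Tm^2)
    swy <- rowSums(W * Y)
    swty <- rowSums(W * Tm * Y)
    det <- sw * swt2 - swt^2
    slope <- (sw * swty - swt * swy) / det
    intercept <- (swt2 * swy - swt * swty) / det
    res <- Y - (outer(slope, t_s) + intercept)
    rss <- rowSums(W * res^2)
    sigma2 <- rss / (nj - 2)
    var_slope <- sigma2 * sw / det
  }

  to_map <- function(v, fill = NA_real_) {
    m <- matrix(fill, nr, nc)
    m[valid] <- v
    m
  }
  structure(list(
    nu_hat = to_map(slope / (2 * pi)),
    phi0_hat = to_map(intercept),
    residual_rms = to_map(sqrt(rss / nj)),
    precision_hz = to_map(sqrt(pmax(var_slope, 0)) / (2 * pi)),
    valid_mask = valid,
    wrap_flag = to_map(as.numeric(wrap)) > 0,
    phi0_forced_zero = phi0_forced_zero,
    geometry = geometry
  ), class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  v <- x$nu_hat[x$valid_mask]
  cat(sprintf("<field_map> %d x %d, %d valid voxels, nu in [%.1f, %.1f] Hz\n",
              nrow(x$nu_hat), ncol(x$nu_hat), sum(x$valid_mask),
              min(v), max(v)))
  invisible(x)
}

#' Compute a field map directly from a single-repetition echo series
#'
#' Convenience wrapper: [incremental_ratios()] followed by [fit_fieldmap()].
#'
#' @inheritParams incremental_ratios
#' @param weighted if `TRUE`, weight each echo by its magnitude (off by
#'   default; the cost function is written unweighted).
#' @return a `field_map`.
#' @export
compute_fieldmap <- function(series, floor_frac = 0.05, weighted = FALSE) {
  inc <- incremental_ratios(series, floor_frac)
  w <- if (weighted) Mod(series$data[, , , 1, drop = TRUE]) else NULL
  fit_fieldmap(inc$phase, series$delta_t, weights = w,
               geometry = series$geometry)
}

#' Estimate T2* from the echo magnitude decay
#'
#' Simple linear least squares of log-magnitude against echo time: the slope
#' is -1/T2*. Voxels with non-positive magnitude at any echo are invalid;
#' voxels with non-decaying magnitude (slope >= 0) get `Inf` with
#' `no_decay_flag` set and an undefined R^2.
#'
#' @param magnitudes numeric array `[rows, cols, echo]` (or a single voxel's
#'   vector of length `n_echoes`).
#' @param te_list echo times (us).
#' @return list with `t2star_us`, `r_squared`, `valid`, `no_decay_flag`
#'   (matrices, or scalars for vector input).
#' @export
estimate_t2star <- function(magnitudes, te_list) {
  vec_in <- is.null(dim(magnitudes))
  if (vec_in) magnitudes <- array(magnitudes, dim = c(1, 1, length(magnitudes)))
  nr <- dim(magnitudes)[1]; nc <- dim(magnitudes)[2]; nj <- dim(magnitudes)[3]
  stopifnot(length(te_list) == nj)
  M <- matrix(magnitudes, nr * nc, nj)
  valid <- rowSums(!is.finite(M) | M <= 0) == 0
  t2 <- rep(NA_real_, nr * nc); r2 <- rep(NA_real_, nr * nc)
  nodecay <- rep(FALSE, nr * nc)
  if (any(valid)) {
    Y <- log(M[valid, , drop = FALSE])
    t <- as.numeric(te_list)
    n <- nj
    sy <- rowSums(Y); sty <- Y %*% t
    st <- sum(t); st2 <- sum(t^2)
    det <- n * st2 - st^2
    slope <- (n * sty - st * sy) / det
    intercept <- (sy - slope * st) / n
    fit <- outer(as.numeric(slope), t) + as.numeric(intercept)
    rss <- rowSums((Y - fit)^2)
    tss <- rowSums((Y - sy / n)^2)
    r2v <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
    t2v <- ifelse(slope < 0, -1 / slope, Inf)
    t2[valid] <- t2v
    r2[valid] <- ifelse(slope < 0, r2v, NA_real_)
    nodecay[valid] <- slope >= 0
  }
  shape <- function(v) matrix(v, nr, nc)
  out <- list(t2star_us = shape(t2), r_squared = shape(r2),
              valid = shape(valid), no_decay_flag = shape(nodecay))
  if (vec_in) out <- lapply(out, function(m) m[1, 1])
  out
}
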