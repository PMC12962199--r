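# Alignment stage: non-rigid registration of echo/repetition magnitude images
# to the first-echo magnitude of the first repetition, warping of the complex
# data, and complex averaging over repetitions.

#' Registration settings
#'
#' Multi-resolution diffusion-regularized demons. `iterations` is ordered
#' coarse to fine. `step_px` caps the per-iteration force (pixels),
#' `update_sigma` smooths each incremental update (fluid-like), `field_sigma`
#' smooths the accumulated field (diffusion-like).
#'
#' @param levels pyramid levels (>= 1).
#' @param iterations integer vector of length `levels`, coarse to fine.
#' @param update_sigma Gaussian sigma (px) for the update field.
#' @param field_sigma Gaussian sigma (px) for the accumulated field.
#' @param step_px maximum displacement per iteration (px).
#' @param per_echo if `TRUE`, every (repetition, echo) magnitude is registered
#'   independently to the reference; the default registers the first-echo
#'   magnitude of each repetition and applies that field to all its echoes
#'   (all echoes of a repetition share the breathing state, and echo-to-echo
#'   T2* contrast would otherwise bias the intensity-based forces).
#' @return list of class `register_settings`.
#' @export
register_settings <- function(levels = 3L, iterations = c(100L, 60L, 30L),
                              update_sigma = 1.0, field_sigma = 2.5,
                              step_px = 1.0, per_echo = FALSE) {
  stopifnot(levels >= 1, length(iterations) == levels)
  structure(as.list(environment()), class = "register_settings")
}

#' Non-rigid registration of two magnitude images
#'
#' Estimates a dense displacement field `u` (backward convention) such that
#' `moving(p + u(p))` matches `fixed(p)`, using multi-resolution Thirion
#' demons with Gaussian regularization. Intensities are normalized internally
#' (99th percentile), so the result is invariant to global scaling.
#'
#' @param moving,fixed numeric matrices of identical size.
#' @param settings a [register_settings()] list.
#' @param geometry optional [geometry2d()] attached to the output.
#' @return object of class `deformation_field`: list with `displacement`
#'   (array `[rows, cols, 2]`, row/col components in px) and `geometry`.
#' @export
register <- function(moving, fixed, settings = register_settings(),
                     geometry = NULL) {
  if (!all(dim(moving) == dim(fixed))) {
    stop("geometry mismatch: moving and fixed images differ in size",
         call. = FALSE)
  }
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0) {
    stop("degenerate input: constant (zero-variance) image cannot be registered",
         call. = FALSE)
  }
  normalize <- function(img) {
    s <- stats::quantile(img, 0.99, names = FALSE)
    if (s <= 0) s <- max(img)
    pmin(img / s, 1.5)
  }
  f <- normalize(fixed); m <- normalize(moving)

  # pyramid, coarse last in the lists below
  fp <- list(f); mp <- list(m)
  for (l in seq_len(settings$levels - 1)) {
    fp[[l + 1]] <- downsample2(smooth_gaussian(fp[[l]], 1))
    mp[[l + 1]] <- downsample2(smooth_gaussian(mp[[l]], 1))
  }

  u <- NULL
  for (l in seq(settings$levels, 1)) {
    fl <- fp[[l]]; ml <- mp[[l]]
    nr <- nrow(fl); nc <- ncol(fl)
    if (is.null(u)) {
      u <- array(0, dim = c(nr, nc, 2))
    } else {
      scale_r <- nr / dim(u)[1]; scale_c <- nc / dim(u)[2]
      u2 <- array(0, dim = c(nr, nc, 2))
      u2[, , 1] <- resize_bilinear(u[, , 1], nr, nc) * scale_r
      u2[, , 2] <- resize_bilinear(u[, , 2], nr, nc) * scale_c
      u <- u2
    }
    iters <- settings$iterations[settings$levels - l + 1]
    u <- demons_level(ml, fl, u, iters, settings)
  }

  # LSQ-style safety: never return a field that worsens the mean squared
  # intensity difference relative to no deformation.
  msd0 <- mean((f - m)^2)
  msd1 <- mean((f - warp_matrix(m, u))^2)
  if (msd1 > msd0) u <- array(0, dim = c(dim(f), 2))

  structure(list(displacement = u, geometry = geometry),
            class = "deformation_field")
}

demons_level <- function(moving, fixed, u, iters, settings) {
  eps <- 1e-12
  step2 <- settings$step_px^2
  for (it in seq_len(iters)) {
    mw <- warp_matrix(moving, u)
    diff <- fixed - mw
    gm <- image_gradient(mw)
    gf <- image_gradient(fixed)
    gr <- (gm$dr + gf$dr) / 2
    gc <- (gm$dc + gf$dc) / 2
    g2 <- gr^2 + gc^2
    denom <- g2 + diff^2 / step2
    ok <- denom > eps
    vr <- matrix(0, nrow(fixed), ncol(fixed))
    vc <- vr
    vr[ok] <- diff[ok] * gr[ok] / denom[ok]
    vc[ok] <- diff[ok] * gc[ok] / denom[ok]
    if (settings$update_sigma > 0) {
      vr <- smooth_gaussian(vr, settings$update_sigma)
      vc <- smooth_gaussian(vc, settings$update_sigma)
    }
    u[, , 1] <- u[, , 1] + vr
    u[, , 2] <- u[, , 2] + vc
    u <- smooth_field(u, settings$field_sigma)
    if (max(abs(vr), abs(vc)) < 1e-4) break
  }
  u
}

#' Warp a complex image by a deformation field
#'
#' Real and imaginary channels are interpolated separately and recombined, so
#' the output phase is the phase of the warped complex signal; wrapped phase
#' values are never interpolated directly.
#'
#' @param image complex matrix.
#' @param field a `deformation_field` (or bare `[rows, cols, 2]` array).
#' @return complex matrix.
#' @export
warp_complex <- function(image, field) {
  disp <- if (inherits(field, "deformation_field")) field$displacement else field
  if (!all(dim(image) == dim(disp)[1:2])) {
    stop("geometry mismatch between image and deformation field", call. = FALSE)
  }
  if (any(!is.finite(disp))) stop("deformation field must be finite", call. = FALSE)
  re <- warp_matrix(Re(image), disp)
  im <- warp_matrix(Im(image), disp)
  complex(real = re, imaginary = im) |> matrix(nrow(image), ncol(image))
}

#' Register and average an echo series
#'
#' Aligns every echo/repetition to the magnitude of (repetition 1, echo 1)
#' and averages the aligned complex signals over repetitions (vector
#' averaging, which implicitly down-weights unreliable low-magnitude voxels
#' and never averages wrapped phase values arithmetically).
#'
#' @param series an `echo_series`.
#' @param settings a [register_settings()] list.
#' @return an `echo_series` with a single repetition. The estimated
#'   deformation fields are attached as attribute `"fields"`.
#' @export
align_and_average <- function(series, settings = register_settings()) {
  stopifnot(inherits(series, "echo_series"))
  d <- series$data
  nr <- dim(d)[1]; nc <- dim(d)[2]; nj <- dim(d)[3]; nrep <- dim(d)[4]
  ref <- Mod(d[, , 1, 1])
  aligned <- d
  fields <- vector("list", nrep)
  zero_field <- array(0, dim = c(nr, nc, 2))
  for (r in seq_len(nrep)) {
    if (settings$per_echo) {
      fields[[r]] <- vector("list", nj)
      for (j in seq_len(nj)) {
        if (r == 1 && j == 1) {
          fields[[r]][[j]] <- zero_field
          next
        }
        fld <- register(Mod(d[, , j, r]), ref, settings)
        fields[[r]][[j]] <- fld$displacement
        aligned[, , j, r] <- warp_complex(d[, , j, r], fld)
      }
    } else {
      if (r == 1) {
        fields[[r]] <- zero_field
        next
      }
      fld <- register(Mod(d[, , 1, r]), ref, settings)
      fields[[r]] <- fld$displacement
      for (j in seq_len(nj)) {
        aligned[, , j, r] <- warp_complex(d[, , j, r], fld)
      }
    }
  }
  avg <- array(complex(real = 0), dim = c(nr, nc, nj, 1))
  for (j in seq_len(nj)) {
    acc <- matrix(complex(real = 0), nr, nc)
    for (r in seq_len(nrep)) acc <- acc + aligned[, , j, r]
    avg[, , j, 1] <- acc / nrep
  }
  out <- echo_series(avg, series$te_list, series$delta_t, series$geometry)
  attr(out, "fields") <- fields
  out
}
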