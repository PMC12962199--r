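# Classical lung segmentation from the first-echo magnitude image. This is a
# deterministic stand-in with the same contract as a learned segmenter: a
# binary region L over which the shim currents are fitted. An external mask
# (e.g. from a clinical network) can be supplied instead via the pipeline's
# mask override.

#' Segmentation settings
#'
#' All thresholds are relative to image intensity quantiles, so the result is
#' invariant under global intensity scaling.
#'
#' @param lung_frac lung candidate threshold as a fraction of the median
#'   in-body intensity.
#' @param min_area_frac minimum component area as a fraction of the body area.
#' @param central_frac half-width of the central column (fraction of image
#'   width) used to reject trachea/airway components by centroid position.
#' @param open_radius radius (px) of the morphological opening applied to the
#'   candidate mask.
#' @return list of class `segment_settings`.
#' @export
segment_settings <- function(lung_frac = 0.55, min_area_frac = 0.02,
                             central_frac = 0.08, open_radius = 1L) {
  structure(as.list(environment()), class = "segment_settings")
}

#' Segment the lungs from a first-echo magnitude image
#'
#' Pipeline: body mask by Otsu thresholding plus hole filling; lung
#' candidates as low-intensity regions inside the body; morphological
#' opening/closing; connected components filtered by area, border contact and
#' a centrality heuristic (components whose centroid lies in the central
#' column are rejected as trachea/airways); the two largest surviving
#' components are kept.
#'
#' @param magnitude numeric matrix (first-echo magnitude).
#' @param settings a [segment_settings()] list.
#' @param geometry optional [geometry2d()] carried into the output.
#' @return object of class `lung_mask`: `mask` (logical matrix),
#'   `component_count`, `body_mask`, `geometry`.
#' @export
segment_lungs <- function(magnitude, settings = segment_settings(),
                          geometry = NULL) {
  if (stats::sd(magnitude) == 0) {
    stop("degenerate input: constant image cannot be segmented", call. = FALSE)
  }
  img <- magnitude / stats::quantile(magnitude, 0.99, names = FALSE)
  img_s <- smooth_gaussian(img, 1)

  thr <- otsu_threshold(img_s)
  body <- img_s > thr
  lab <- label_components(body, conn = 4L)
  if (attr(lab, "n") == 0L) {
    stop("empty-mask error: no body region found (image may be noise only)",
         call. = FALSE)
  }
  sizes <- tabulate(lab[lab > 0L], attr(lab, "n"))
  body <- lab == which.max(sizes)
  body <- fill_holes(close_mask(body, 2L))

  body_med <- stats::median(img_s[body])
  cand <- body & img_s < settings$lung_frac * body_med
  cand <- open_mask(cand, settings$open_radius)
  cand <- close_mask(cand, 1L)
  cand <- cand & body

  lab <- label_components(cand, conn = 4L)
  ncomp <- attr(lab, "n")
  if (ncomp == 0L) {
    stop("empty-mask error: no lung candidate regions inside the body ",
         "(check image contrast)", call. = FALSE)
  }
  nrm <- nrow(img); ncm <- ncol(img)
  min_area <- settings$min_area_frac * sum(body)
  keep <- integer(0)
  areas <- numeric(0)
  for (k in seq_len(ncomp)) {
    comp <- lab == k
    a <- sum(comp)
    if (a < min_area) next
    idx <- which(comp, arr.ind = TRUE)
    # border contact
    if (any(idx[, 1] %in% c(1L, nrm)) || any(idx[, 2] %in% c(1L, ncm))) next
    # trachea/central-airway heuristic: centroid inside the central column
    ccol <- mean(idx[, 2])
    if (abs(ccol - (ncm + 1) / 2) < settings$central_frac * ncm) next
    keep <- c(keep, k)
    areas <- c(areas, a)
  }
  if (length(keep) == 0L) {
    stop("empty-mask error: all candidate regions rejected by area/position ",
         "constraints", call. = FALSE)
  }
  keep <- keep[order(areas, decreasing = TRUE)][seq_len(min(2L, length(keep)))]
  mask <- matrix(lab %in% keep, nrm, ncm)

  structure(list(mask = mask, component_count = length(keep),
                 body_mask = body, geometry = geometry),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %d x %d, %d component(s), %d voxels\n",
              nrow(x$mask), ncol(x$mask), x$component_count, sum(x$mask)))
  invisible(x)
}

#' Wrap an externally supplied binary mask as a lung mask
#'
#' Hook for plugging in a learned segmenter: any 0/1 image (e.g. read with
#' [read_nifti()]) bypasses the classical pipeline.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param geometry optional [geometry2d()].
#' @return a `lung_mask`.
#' @export
as_lung_mask <- function(mask, geometry = NULL) {
  m <- mask > 0
  lab <- label_components(m, conn = 4L)
  structure(list(mask = m, component_count = attr(lab, "n"),
                 body_mask = NULL, geometry = geometry),
            class = "lung_mask")
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical matrices.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  2 * sum(a & b) / (sum(a) + sum(b))
}
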