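# Zeroth- to second-order spherical-harmonic shim model, restricted to the
# lung mask. For a single coronal slice the anterior-posterior position is an
# arbitrary offset, so y = 0 is substituted into the basis; the three
# functions linear in y (indices 3, 6, 8) vanish identically and are excluded
# from the optimization, their coefficients pinned to zero.

# index:      0  1  2  3  4                 5   6   7        8
# function:   1  z  x  y  z^2-(x^2+y^2)/2   zx  zy  x^2-y^2  xy
SHIM_TERMS <- c("1", "z", "x", "y", "z2_r2", "zx", "zy", "x2y2", "xy")
Y_DEPENDENT <- c(3L, 6L, 8L)  # 0-based indices eliminated by y = 0

#' Build the spherical-harmonic shim basis on an image grid
#'
#' Samples the nine zeroth- to second-order harmonic field shapes
#' `[1, z, x, y, z^2 - (x^2 + y^2)/2, zx, zy, x^2 - y^2, xy]` at every voxel
#' position (x, z in mm from isocenter, y = 0). Columns 3, 6 and 8 (0-based)
#' are identically zero under the y = 0 convention.
#'
#' @param geometry a [geometry2d()].
#' @param order harmonic order, at most 2 (order 0 -> 1 column, 1 -> 4,
#'   2 -> 9).
#' @return object of class `shim_basis`: `A` (matrix, voxels x columns, in
#'   column-major voxel order), `terms`, `excluded` (0-based indices of
#'   y-dependent columns present), `geometry`, `units` (mm powers per
#'   column).
#' @export
build_basis <- function(geometry, order = 2L) {
  if (order < 0 || order > 2) stop("order must be 0, 1 or 2", call. = FALSE)
  g <- coordinate_grids(geometry)
  x <- as.numeric(g$x); z <- as.numeric(g$z)
  y <- 0
  cols <- list(
    rep(1, length(x)), z, x, rep(y, length(x)),
    z^2 - (x^2 + y^2) / 2, z * x, z * y, x^2 - y^2, x * y
  )
  n_cols <- c(1L, 4L, 9L)[order + 1]
  A <- do.call(cbind, cols[seq_len(n_cols)])
  colnames(A) <- SHIM_TERMS[seq_len(n_cols)]
  structure(list(
    A = A,
    terms = SHIM_TERMS[seq_len(n_cols)],
    excluded = Y_DEPENDENT[Y_DEPENDENT < n_cols],
    geometry = geometry,
    units = c("", "mm", "mm", "mm", "mm^2", "mm^2", "mm^2", "mm^2",
              "mm^2")[seq_len(n_cols)]
  ), class = "shim_basis")
}

#' Evaluate the shim basis at arbitrary coordinates
#'
#' @param x,z coordinates in mm (y is fixed at 0).
#' @return numeric matrix with 9 columns in the canonical order.
#' @export
shim_basis_at <- function(x, z) {
  y <- 0
  cbind(1, z, x, y, z^2 - (x^2 + y^2) / 2, z * x, z * y, x^2 - y^2, x * y,
        deparse.level = 0)
}

#' Solve the mask-restricted shim problem
#'
#' Linear least squares `min_c sum_{j in L} (nu_j - (a . c)_j)^2` over the
#' voxels of the lung mask intersected with the field map's valid mask. The
#' y-dependent columns are removed from the design and their coefficients
#' returned as exactly 0. The design is column-scaled internally for
#' conditioning; coefficients are reported on the unnormalized basis, i.e.
#' in Hz, Hz/mm and Hz/mm^2.
#'
#' @param field a `field_map`.
#' @param mask a `lung_mask` (or logical matrix).
#' @param basis a `shim_basis` built on the same geometry.
#' @param excluded 0-based indices excluded from the optimization (default
#'   the basis's y-dependent set {3, 6, 8}).
#' @return object of class `shim_solution`: `coefficients` (length 9, named),
#'   `excluded`, `residual_ss` (in-mask residual sum of squares, Hz^2),
#'   `pre_ss` (sum of squares of the unshimmed in-mask field),
#'   `condition_number` (of the scaled retained design), `n_voxels`.
#' @export
solve_shim <- function(field, mask, basis, excluded = NULL) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask > 0
  if (!all(dim(m) == dim(field$nu_hat))) {
    stop("geometry mismatch between mask and field map", call. = FALSE)
  }
  if (is.null(excluded)) excluded <- basis$excluded
  sel <- as.logical(m) & as.logical(field$valid_mask)
  if (!any(sel)) stop("empty mask: no valid in-mask voxels", call. = FALSE)
  retained <- setdiff(seq_len(ncol(basis$A)) - 1L, excluded)
  if (sum(sel) < length(retained)) {
    stop("too few in-mask voxels (", sum(sel), ") for ", length(retained),
         " shim unknowns", call. = FALSE)
  }
  A <- basis$A[sel, retained + 1L, drop = FALSE]
  b <- field$nu_hat[sel]

  col_scale <- apply(abs(A), 2, max)
  col_scale[col_scale == 0] <- 1
  As <- sweep(A, 2, col_scale, "/")
  qrd <- qr(As)
  if (qrd$rank < ncol(As)) {
    bad <- basis$terms[retained + 1L][qrd$pivot[-seq_len(qrd$rank)]]
    stop("rank-deficient shim design (mask degenerate along: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  cs <- qr.coef(qrd, b)
  coef_retained <- cs / col_scale
  coefficients <- stats::setNames(numeric(ncol(basis$A)), basis$terms)
  coefficients[retained + 1L] <- coef_retained

  res <- b - drop(A %*% coef_retained)
  structure(list(
    coefficients = coefficients,
    excluded = excluded,
    residual_ss = sum(res^2),
    pre_ss = sum(b^2),
    condition_number = kappa(qr.R(qrd), exact = TRUE),
    n_voxels = sum(sel)
  ), class = "shim_solution")
}

#' @export
print.shim_solution <- function(x, ...) {
  cat("<shim_solution>\n")
  cat(sprintf("  f0 offset        : %10.3f Hz\n", x$coefficients[1]))
  cat(sprintf("  z, x             : %10.4f %10.4f Hz/mm\n",
              x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  z2-r2/2, zx, x2-y2: %9.6f %10.6f %10.6f Hz/mm^2\n",
              x$coefficients[5], x$coefficients[6], x$coefficients[8]))
  cat(sprintf("  in-mask residual RMS %.2f Hz over %d voxels (pre %.2f Hz)\n",
              sqrt(x$residual_ss / x$n_voxels), x$n_voxels,
              sqrt(x$pre_ss / x$n_voxels)))
  invisible(x)
}

#' Predict the residual field after applying a shim solution
#'
#' Subtracts the modeled harmonic field `a . c` from the measured field map;
#' the valid mask is preserved.
#'
#' @param field a `field_map`.
#' @param solution a `shim_solution`.
#' @param basis the `shim_basis` the solution was fitted with.
#' @return a `field_map` whose `nu_hat` is the per-voxel residual.
#' @export
predict_residual <- function(field, solution, basis) {
  if (!all(dim(field$nu_hat) == basis$geometry$matrix)) {
    stop("geometry mismatch between field map and basis", call. = FALSE)
  }
  correction <- matrix(drop(basis$A %*% solution$coefficients[seq_len(ncol(basis$A))]),
                       nrow(field$nu_hat), ncol(field$nu_hat))
  out <- field
  out$nu_hat <- field$nu_hat - correction
  out
}

# ---- shim configuration file ----------------------------------------------

SHIM_CONFIG_KEYS <- c("f0_offset_hz", "c1_z_hz_per_mm", "c2_x_hz_per_mm",
                      "c4_z2_hz_per_mm2", "c5_zx_hz_per_mm2",
                      "c7_x2y2_hz_per_mm2")

#' Write a shim solution to a plain-text configuration file
#'
#' Key = value format with a metadata header and a geometry block; the global
#' frequency term is reported separately as a center-frequency offset
#' (`f0_offset_hz`). Floats are printed with 6 decimals; a write -> read
#' round trip reproduces the printed values exactly.
#'
#' @param solution a `shim_solution`.
#' @param path output file path.
#' @param geometry optional [geometry2d()] written into the geometry block.
#' @return `path`, invisibly.
#' @export
write_shim_config <- function(solution, path, geometry = NULL) {
  vals <- solution$coefficients[c(1, 2, 3, 5, 6, 8)]
  lines <- c(
    "# lungshim configuration",
    paste0("# created = ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"), "Z"),
    "format_version = 1"
  )
  if (!is.null(geometry)) {
    lines <- c(lines,
               sprintf("matrix_rows = %d", geometry$matrix[1]),
               sprintf("matrix_cols = %d", geometry$matrix[2]),
               sprintf("fov_z_mm = %.6f", geometry$fov_mm[1]),
               sprintf("fov_x_mm = %.6f", geometry$fov_mm[2]),
               sprintf("slice_y_mm = %.6f", geometry$slice_y_mm))
  }
  lines <- c(lines, sprintf("%s = %.6f", SHIM_CONFIG_KEYS, vals))
  writeLines(lines, path)
  invisible(path)
}

#' Read a shim configuration file
#'
#' @param path path to a file written by [write_shim_config()] (or by hand in
#'   the same key = value format).
#' @return a `shim_solution` with the parsed coefficients (excluded set
#'   {3, 6, 8} at zero) and, if present, a `geometry` element.
#' @export
read_shim_config <- function(path) {
  if (!file.exists(path)) stop("shim config file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- grepl("=", raw, fixed = TRUE) & !grepl("^\\s*#", raw)
  kv <- raw[keep]
  bad <- kv[!grepl("^\\s*[A-Za-z0-9_]+\\s*=\\s*[-+0-9.eE]+\\s*$", kv)]
  if (length(bad) > 0) {
    stop("malformed shim config line(s): ", paste(sQuote(trimws(bad)), collapse = ", "),
         call. = FALSE)
  }
  keys <- trimws(sub("=.*", "", kv))
  vals <- as.numeric(trimws(sub(".*=", "", kv)))
  names(vals) <- keys
  missing <- setdiff(SHIM_CONFIG_KEYS, keys)
  if (length(missing) > 0) {
    stop("shim config is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  coefficients <- stats::setNames(numeric(9), SHIM_TERMS)
  coefficients[c(1, 2, 3, 5, 6, 8)] <- vals[SHIM_CONFIG_KEYS]
  geometry <- NULL
  if (all(c("matrix_rows", "matrix_cols", "fov_z_mm", "fov_x_mm") %in% keys)) {
    geometry <- geometry2d(c(vals[["matrix_rows"]], vals[["matrix_cols"]]),
                           c(vals[["fov_z_mm"]], vals[["fov_x_mm"]]),
                           if ("slice_y_mm" %in% keys) vals[["slice_y_mm"]] else 0)
  }
  structure(list(coefficients = coefficients, excluded = Y_DEPENDENT,
                 residual_ss = NA_real_, pre_ss = NA_real_,
                 condition_number = NA_real_, n_voxels = NA_integer_,
                 geometry = geometry),
            class = "shim_solution")
}
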