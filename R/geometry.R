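#' 2D coronal image geometry
#'
#' Describes the sampling grid of a single coronal slice. Rows index the
#' head--foot direction (z, superior at the top of the image), columns index
#' left--right (x). The physical origin (x = 0, z = 0) is the image centre
#' (magnet isocenter); x increases with column index and z decreases with row
#' index. The anterior--posterior position of the slice is a constant offset
#' `slice_y_mm` (treated as y = 0 by the shim basis, see [build_basis()]).
#'
#' @param matrix integer vector `c(rows, cols)`, both >= 1.
#' @param fov_mm numeric vector `c(fov_z, fov_x)` field of view in mm.
#' @param slice_y_mm anterior--posterior offset of the slice in mm.
#' @return An object of class `geometry2d` with elements `matrix`, `fov_mm`,
#'   `slice_y_mm` and the derived `pixel_mm` (mm per pixel along rows, cols).
#' @examples
#' g <- geometry2d(c(128, 128), c(450, 450))
#' g$pixel_mm
#' @export
geometry2d <- function(matrix = c(128L, 128L), fov_mm = c(450, 450),
                       slice_y_mm = 0) {
  matrix <- as.integer(matrix)
  if (length(matrix) != 2 || any(!is.finite(matrix)) || any(matrix < 1)) {
    stop("invalid geometry: 'matrix' must be two positive integers",
         call. = FALSE)
  }
  fov_mm <- as.numeric(fov_mm)
  if (length(fov_mm) != 2 || any(!is.finite(fov_mm)) || any(fov_mm <= 0)) {
    stop("invalid geometry: 'fov_mm' must be two positive lengths",
         call. = FALSE)
  }
  structure(list(
    matrix = matrix,
    fov_mm = fov_mm,
    slice_y_mm = as.numeric(slice_y_mm),
    pixel_mm = fov_mm / matrix
  ), class = "geometry2d")
}

#' @export
print.geometry2d <- function(x, ...) {
  cat(sprintf("<geometry2d> %d x %d, FOV %.1f x %.1f mm, pixel %.3f x %.3f mm, y = %.1f mm\n",
              x$matrix[1], x$matrix[2], x$fov_mm[1], x$fov_mm[2],
              x$pixel_mm[1], x$pixel_mm[2], x$slice_y_mm))
  invisible(x)
}

#' Physical coordinate grids for a geometry
#'
#' @param geometry a [geometry2d()] object.
#' @return list with matrices `x` and `z` (mm), each `rows x cols`.
#' @keywords internal
coordinate_grids <- function(geometry) {
  nr <- geometry$matrix[1]; nc <- geometry$matrix[2]
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  z <- -(seq_len(nr) - rc) * geometry$pixel_mm[1]   # superior (z > 0) at top
  x <- (seq_len(nc) - cc) * geometry$pixel_mm[2]
  list(x = matrix(x, nr, nc, byrow = TRUE), z = matrix(z, nr, nc))
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(a$matrix == b$matrix) && all(abs(a$fov_mm - b$fov_mm) < tol)
}

stopifnot_same_geometry <- function(a, b) {
  if (!same_geometry(a, b)) stop("geometry mismatch between inputs", call. = FALSE)
}
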