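# Low-level grid operations shared by the phantom, registration and
# segmentation stages. All images are plain R matrices [rows, cols];
# displacement fields are arrays [rows, cols, 2] with component 1 along rows
# and component 2 along columns, in pixels, backward convention:
# warped(p) = image(p + u(p)).

#' Bilinear interpolation on a matrix
#'
#' Samples `img` at (possibly fractional) row/column positions with
#' replicate-border handling. Exact (no floating error) at integer positions.
#'
#' @param img numeric or complex matrix.
#' @param qr,qc matrices/vectors of query row and column positions (1-based).
#' @return values with the shape of `qr`.
#' @keywords internal
interp_bilinear <- function(img, qr, qc) {
  nr <- nrow(img); nc <- ncol(img)
  qr <- pmin(pmax(qr, 1), nr)
  qc <- pmin(pmax(qc, 1), nc)
  r0 <- if (nr == 1L) qr * 0 + 1 else pmin(floor(qr), nr - 1L)
  c0 <- if (nc == 1L) qc * 0 + 1 else pmin(floor(qc), nc - 1L)
  fr <- qr - r0; fc <- qc - c0
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  i00 <- (c0 - 1) * nr + r0
  i10 <- (c0 - 1) * nr + r1
  i01 <- (c1 - 1) * nr + r0
  i11 <- (c1 - 1) * nr + r1
  v <- img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
  dim(v) <- dim(qr)
  v
}

#' Warp a matrix by a displacement field (backward convention)
#' @keywords internal
warp_matrix <- function(img, disp) {
  nr <- nrow(img); nc <- ncol(img)
  base_r <- matrix(seq_len(nr), nr, nc)
  base_c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  interp_bilinear(img, base_r + disp[, , 1], base_c + disp[, , 2])
}

# Separable Gaussian smoothing via banded kernel matrices with renormalized
# (replicate-equivalent) borders. sigma in pixels; sigma <= 0 is a no-op.
gaussian_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  offs <- -half:half
  w <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (k in seq_along(offs)) {
    idx <- seq_len(n) + offs[k]
    ok <- idx >= 1 & idx <= n
    K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] + w[k]
  }
  K / rowSums(K)
}

#' @keywords internal
smooth_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Kr <- gaussian_kernel_matrix(nrow(img), sigma)
  Kc <- gaussian_kernel_matrix(ncol(img), sigma)
  Kr %*% img %*% t(Kc)
}

smooth_field <- function(disp, sigma) {
  if (sigma <= 0) return(disp)
  disp[, , 1] <- smooth_gaussian(disp[, , 1], sigma)
  disp[, , 2] <- smooth_gaussian(disp[, , 2], sigma)
  disp
}

# Central-difference spatial gradient, replicate borders.
image_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1, seq_len(nr - 1)), , drop = FALSE]
  dn <- img[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  lf <- img[, c(1, seq_len(nc - 1)), drop = FALSE]
  rt <- img[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  list(dr = (dn - up) / 2, dc = (rt - lf) / 2)
}

# 2x2 block-mean downsampling (pads by replication for odd sizes).
downsample2 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr %% 2 == 1) img <- rbind(img, img[nr, , drop = FALSE])
  if (nc %% 2 == 1) img <- cbind(img, img[, ncol(img), drop = FALSE])
  nr2 <- nrow(img) / 2; nc2 <- ncol(img) / 2
  (img[2 * seq_len(nr2) - 1, 2 * seq_len(nc2) - 1, drop = FALSE] +
     img[2 * seq_len(nr2), 2 * seq_len(nc2) - 1, drop = FALSE] +
     img[2 * seq_len(nr2) - 1, 2 * seq_len(nc2), drop = FALSE] +
     img[2 * seq_len(nr2), 2 * seq_len(nc2), drop = FALSE]) / 4
}

# Bilinear resize to target size (used to upsample pyramid displacement).
resize_bilinear <- function(img, nr_out, nc_out) {
  nr <- nrow(img); nc <- ncol(img)
  qr <- if (nr_out == 1) matrix(1, 1, nc_out) else
    matrix(seq(1, nr, length.out = nr_out), nr_out, nc_out)
  qc <- if (nc_out == 1) matrix(1, nr_out, 1) else
    matrix(seq(1, nc, length.out = nc_out), nr_out, nc_out, byrow = TRUE)
  interp_bilinear(img, qr, qc)
}

# ---- binary morphology & labeling -----------------------------------------

shift_mask <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

# 4/8-neighborhood dilation/erosion, repeated `r` times for a radius-r
# structuring element (diamond for conn = 4, square for conn = 8).
dilate_mask <- function(m, r = 1L, conn = 4L) {
  offs <- if (conn == 4L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)) else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (i in seq_len(r)) {
    acc <- m
    for (o in offs) acc <- acc | shift_mask(m, o[1], o[2], FALSE)
    m <- acc
  }
  m
}

erode_mask <- function(m, r = 1L, conn = 4L) !dilate_mask(!m, r, conn)

open_mask <- function(m, r = 1L, conn = 4L) dilate_mask(erode_mask(m, r, conn), r, conn)
close_mask <- function(m, r = 1L, conn = 4L) erode_mask(dilate_mask(m, r, conn), r, conn)

#' Connected-component labeling of a binary matrix
#'
#' Two-pass union-find labeling with 4- or 8-connectivity.
#'
#' @param mask logical matrix.
#' @param conn 4 or 8.
#' @return integer matrix of labels (0 = background), with attribute
#'   `n` giving the number of components.
#' @keywords internal
label_components <- function(mask, conn = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!mask[rr, cc]) next
      up <- if (rr > 1L) lab[rr - 1L, cc] else 0L
      lf <- if (cc > 1L) lab[rr, cc - 1L] else 0L
      nb <- c(up, lf)
      if (conn == 8L && cc > 1L) {
        if (rr > 1L) nb <- c(nb, lab[rr - 1L, cc - 1L])
        if (rr < nr) nb <- c(nb, lab[rr + 1L, cc - 1L])
      }
      nb <- nb[nb > 0L]
      if (length(nb) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[rr, cc] <- nxt
      } else {
        m <- min(nb)
        lab[rr, cc] <- m
        for (b in nb) {
          rb <- find_root(b); rm <- find_root(m)
          if (rb != rm) parent[max(rb, rm)] <- min(rb, rm)
        }
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find_root, integer(1))
    remap <- integer(nxt)
    uroots <- sort(unique(roots))
    remap[uroots] <- seq_along(uroots)
    pos <- which(lab > 0L)
    lab[pos] <- remap[roots[lab[pos]]]
    attr(lab, "n") <- length(uroots)
  } else {
    attr(lab, "n") <- 0L
  }
  lab
}

# Fill holes: anything not reachable from the border through background.
fill_holes <- function(mask) {
  bg <- label_components(!mask, conn = 4L)
  if (attr(bg, "n") == 0L) return(mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  hole <- bg > 0L & !(bg %in% border_labels)
  dim(hole) <- dim(mask)
  mask | hole
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}
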