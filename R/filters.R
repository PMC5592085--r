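# Low-level separable/box/disc averaging filters used throughout the
# pipeline. All filters use symmetric (reflect-including-edge) padding so
# that no spurious extrema appear at the field-of-view rim.

#' Reflected index vector for symmetric padding
#'
#' Maps arbitrary (possibly out-of-range) 1-based indices onto 1..n by
#' symmetric reflection including the edge sample, folding as many times
#' as needed (margins may exceed the image size).
#'
#' @param idx integer vector of indices (any range)
#' @param n axis length
#' @return integer vector in 1..n
#' @keywords internal
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep.int(1L, length(idx)))
  p <- 2L * n
  r <- ((idx - 1L) %% p + p) %% p
  ifelse(r >= n, p - 1L - r, r) + 1L
}

#' Pad a matrix by symmetric reflection
#'
#' @param m numeric matrix
#' @param top,bottom,left,right margin sizes in pixels
#' @return padded matrix
#' @keywords internal
pad_reflect <- function(m, top, bottom = top, left = top, right = left) {
  ri <- reflect_index(seq.int(1L - top, nrow(m) + bottom), nrow(m))
  ci <- reflect_index(seq.int(1L - left, ncol(m) + right), ncol(m))
  m[ri, ci, drop = FALSE]
}

# summed-area table with a leading zero row/column, so that
# sat[i + 1, j + 1] = sum(m[1:i, 1:j])
.sat <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

#' Rectangular (box) averaging filter
#'
#' Mean over a `kr` x `kc` window, symmetric-reflect padded, computed with a
#' summed-area table. For even kernel sizes the window extends
#' `k %/% 2` pixels before and `k - 1 - k %/% 2` after the center.
#'
#' @param m numeric matrix
#' @param kr,kc kernel height (rows) and width (columns) in pixels
#' @return matrix of the same shape as `m`
#' @export
box_mean <- function(m, kr, kc) {
  stopifnot(kr >= 1, kc >= 1)
  lr <- kr %/% 2L; lc <- kc %/% 2L
  p <- pad_reflect(m, top = lr, bottom = kr - 1L - lr,
                   left = lc, right = kc - 1L - lc)
  s <- .sat(p)
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr); ci <- seq_len(nc)
  (s[ri + kr, ci + kc, drop = FALSE] - s[ri, ci + kc, drop = FALSE] -
     s[ri + kr, ci, drop = FALSE] + s[ri, ci, drop = FALSE]) / (kr * kc)
}

#' Circular (disc) averaging filter
#'
#' Mean over the Euclidean disc \{(dy,dx): dy^2 + dx^2 <= r^2\}, with
#' symmetric-reflect padding. Implemented as a sum of per-row running
#' window sums, so it is exact (no FFT round-off).
#'
#' @param m numeric matrix
#' @param r disc radius in pixels
#' @return matrix of the same shape as `m`
#' @export
disc_mean <- function(m, r) {
  stopifnot(r >= 1)
  r <- as.integer(r)
  p <- pad_reflect(m, top = r, bottom = r, left = r, right = r)
  # per-row cumulative sums with a leading zero column:
  # rc[i, j + 1] = sum(p[i, 1:j])
  rc <- cbind(0, t(apply(p, 1L, cumsum)))
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr); ci <- seq_len(nc)
  acc <- matrix(0, nr, nc)
  npix <- 0L
  for (dy in -r:r) {
    w <- floor(sqrt(r^2 - dy^2))
    npix <- npix + 2L * w + 1L
    # window sum over columns (j - w)..(j + w) at row offset dy;
    # padded coordinates: row i + r + dy, cols ci + r +/- w
    acc <- acc + rc[ri + r + dy, ci + r + w + 1L, drop = FALSE] -
      rc[ri + r + dy, ci + r - w, drop = FALSE]
  }
  acc / npix
}

#' Separable Gaussian blur
#'
#' @param m numeric matrix
#' @param sigma standard deviation in pixels; kernel truncated at 3 sigma
#' @return blurred matrix, same shape
#' @keywords internal
gaussian_blur <- function(m, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  w <- w / sum(w)
  p <- pad_reflect(m, top = rad, bottom = rad, left = rad, right = rad)
  nrp <- nrow(p)
  ri <- (rad + 1L):(nrp - rad)
  h <- matrix(0, length(ri), ncol(p))
  for (k in -rad:rad) h <- h + w[k + rad + 1L] * p[ri + k, , drop = FALSE]
  ci <- (rad + 1L):(ncol(p) - rad)
  out <- matrix(0, nrow(m), ncol(m))
  for (k in -rad:rad) out <- out + w[k + rad + 1L] * h[, ci + k, drop = FALSE]
  out
}

#' Euclidean disc structuring element
#'
#' Binary matrix of the offsets \{(dy,dx): dy^2 + dx^2 <= r^2\}.
#'
#' @param r radius in pixels
#' @return (2r+1) x (2r+1) 0/1 matrix
#' @keywords internal
disc_kernel <- function(r) {
  d <- -r:r
  outer(d, d, function(a, b) as.numeric(a * a + b * b <= r * r))
}
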