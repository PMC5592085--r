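# Field-of-view detection and scale normalization. The working frame for
# every downstream parameter is the image resized (bicubic) so that the
# retina diameter equals 540 pixels.

#' Read a fundus photograph into a (row, col, channel) array
#'
#' Reads PNG/JPEG/TIFF via EBImage; the first three channels are taken as
#' R, G, B and values are rescaled to the 0..255 range. Non-8-bit input is
#' linearly rescaled with a warning.
#'
#' @param path image file path
#' @return numeric array of dim (rows, cols, 3), values in 0..255
#' @export
read_fundus <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) d <- array(rep(d, 3L), c(dim(d), 3L))
  if (dim(d)[3L] < 3L) stop("need at least 3 channels, got ", dim(d)[3L])
  d <- d[, , 1:3, drop = FALSE]
  a <- aperm(d, c(2L, 1L, 3L))  # EBImage stores (x, y); we use (row, col)
  mx <- max(a)
  if (mx > 1 + 1e-9) {
    warning("input not 8-bit scaled; linearly rescaling to 0..255")
    a <- a / mx * 255
  } else {
    a <- a * 255
  }
  a
}

#' Write a (row, col, channel) fundus array to an image file
#'
#' Inverse of [read_fundus()]; format chosen by the file extension
#' (PNG/JPEG/TIFF).
#'
#' @param rgb numeric array (rows, cols, 3), values 0..255
#' @param path output file path
#' @return the path, invisibly
#' @export
write_fundus <- function(rgb, path) {
  img <- EBImage::Image(aperm(rgb / 255, c(2L, 1L, 3L)),
                        colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Detect the circular field of view of a fundus image
#'
#' Binarizes the channel sum at 10% of its maximum, keeps the largest
#' connected component and fills holes. The retina diameter is the larger
#' side of the component bounding box.
#'
#' @param rgb (rows, cols, >=3) array, 8-bit scale
#' @return object of class `fov_mask`: list with `mask` (logical matrix),
#'   `diameter_px`, `center` = c(row, col) centroid
#' @export
detect_fov <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] >= 3L,
            min(dim(rgb)[1:2]) >= 64L)
  s <- rgb[, , 1L] + rgb[, , 2L] + rgb[, , 3L]
  mx <- max(s)
  if (mx <= 0) stop("FOV_NOT_FOUND: image is entirely dark")
  b <- s > 0.1 * mx
  lab <- EBImage::bwlabel(b * 1)
  if (max(lab) < 1) stop("FOV_NOT_FOUND: no bright region")
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask * 1) > 0
  if (sum(mask) < 0.10 * length(mask))
    stop("FOV_NOT_FOUND: candidate region covers < 10% of the frame")
  rr <- range(which(rowSums(mask) > 0L))
  cr <- range(which(colSums(mask) > 0L))
  diam <- max(diff(rr), diff(cr)) + 1
  idx <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask, diameter_px = diam,
                 center = c(mean(idx[, 1L]), mean(idx[, 2L]))),
            class = "fov_mask")
}

# Keys bicubic kernel, a = -0.5 (the usual "cubic convolution")
.keys <- function(x) {
  x <- abs(x)
  ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

# one-axis bicubic interpolation weights for an output grid of length
# nout sampled at scale `s` (input coords of output pixel centers)
.cubic_axis <- function(nin, nout, s) {
  # pixel-center alignment: output pixel i (1-based) maps to input
  # coordinate (i - 0.5)/s + 0.5
  x <- (seq_len(nout) - 0.5) / s + 0.5
  i0 <- floor(x) - 1L
  w <- sapply(0:3, function(k) .keys(x - (i0 + k)))
  if (is.null(dim(w))) w <- matrix(w, nrow = 1L)
  w <- w / rowSums(w)
  idx <- sapply(0:3, function(k) pmin(pmax(i0 + k, 1L), nin))
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  list(idx = idx, w = w)
}

#' Bicubic resampling of a matrix
#'
#' Separable Keys cubic-convolution (a = -0.5) resampling with
#' pixel-center alignment and edge clamping.
#'
#' @param m numeric matrix
#' @param nr,nc output size (rows, cols)
#' @return resampled matrix of dim (nr, nc)
#' @keywords internal
resize_bicubic <- function(m, nr, nc) {
  sr <- nr / nrow(m); sc <- nc / ncol(m)
  ax_r <- .cubic_axis(nrow(m), nr, sr)
  ax_c <- .cubic_axis(ncol(m), nc, sc)
  h <- matrix(0, nr, ncol(m))
  for (k in 1:4)
    h <- h + ax_r$w[, k] * m[ax_r$idx[, k], , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in 1:4)
    out <- out + t(t(h[, ax_c$idx[, k], drop = FALSE]) * ax_c$w[, k])
  out
}

#' Normalize a fundus image to the 540-pixel retina-diameter frame
#'
#' Resizes the image (bicubic) by 540 / retina diameter so that all
#' downstream filter sizes are resolution independent; the FOV is
#' re-detected on the result.
#'
#' @param rgb (rows, cols, 3) array, 8-bit scale
#' @param fov `fov_mask` from [detect_fov()]; detected if missing
#' @param target target retina diameter in pixels (default 540)
#' @return object of class `working_image`: list with `rgb` (normalized
#'   array), `fov` (re-detected), `scale` (normalized px per original px),
#'   `original_shape`
#' @export
normalize_scale <- function(rgb, fov = NULL, target = 540) {
  if (is.null(fov)) fov <- detect_fov(rgb)
  sc <- target / fov$diameter_px
  nr <- max(8L, round(dim(rgb)[1L] * sc))
  nc <- max(8L, round(dim(rgb)[2L] * sc))
  out <- array(0, c(nr, nc, 3L))
  for (ch in 1:3) {
    out[, , ch] <- if (sc == 1) rgb[, , ch] else
      resize_bicubic(rgb[, , ch], nr, nc)
  }
  out[out < 0] <- 0
  out[out > 255] <- 255
  structure(list(rgb = out, fov = detect_fov(out), scale = sc,
                 original_shape = dim(rgb)[1:2]),
            class = "working_image")
}

#' Complement of the green channel
#'
#' The complemented green channel G_c = 255 - G gives the best
#' vessel-background contrast and is the input to vessel enhancement.
#'
#' @param x a `working_image`, a (rows, cols, 3) array, or a green-channel
#'   matrix
#' @return matrix, values in 0..255
#' @export
complement_green <- function(x) {
  g <- if (inherits(x, "working_image")) x$rgb[, , 2L]
  else if (length(dim(x)) == 3L) x[, , 2L]
  else x
  255 - g
}
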