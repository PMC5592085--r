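# Independent brute-force oracles. These deliberately share no code with
# the package internals: padding, window sums and morphology are written
# as direct definitions.

# symmetric reflection (including the edge sample) of one index onto
# 1..n: the padded sequence is ..., 2, 1, | 1, 2, ..., n, | n, n-1, ...
bf_reflect <- function(i, n) {
  if (n == 1L) return(1L)
  j <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n)
  if (j >= n) 2L * n - 1L - j + 1L else j + 1L
}

bf_pad <- function(m, mt, mb, ml, mr) {
  ri <- vapply(seq.int(1L - mt, nrow(m) + mb), bf_reflect, integer(1), n = nrow(m))
  ci <- vapply(seq.int(1L - ml, ncol(m) + mr), bf_reflect, integer(1), n = ncol(m))
  m[ri, ci, drop = FALSE]
}

# box mean by direct window summation, offsets -(k %/% 2) .. k - 1 - k %/% 2
bf_box_mean <- function(m, kr, kc) {
  lr <- kr %/% 2L; lc <- kc %/% 2L
  p <- bf_pad(m, lr, kr - 1L - lr, lc, kc - 1L - lc)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[i, j] <- mean(p[i:(i + kr - 1L), j:(j + kc - 1L)])
  out
}

# circular mean by direct masked summation
bf_disc_mean <- function(m, r) {
  p <- bf_pad(m, r, r, r, r)
  d <- -r:r
  disc <- which(outer(d, d, function(a, b) a * a + b * b <= r * r),
                arr.ind = TRUE)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[i, j] <- mean(p[cbind(i - 1L + disc[, 1L], j - 1L + disc[, 2L])])
  out
}

# white top-hat with clipped-neighbourhood grayscale morphology
bf_tophat <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  d <- -r:r
  off <- which(outer(d, d, function(a, b) a * a + b * b <= r * r),
               arr.ind = TRUE) - (r + 1L)
  er <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + off[, 1L]; jj <- j + off[, 2L]
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    er[i, j] <- min(m[cbind(ii[ok], jj[ok])])
  }
  di <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + off[, 1L]; jj <- j + off[, 2L]
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    di[i, j] <- max(er[cbind(ii[ok], jj[ok])])
  }
  m - di
}

# symmetric mean average boundary distance, all-pairs double loop
bf_mad <- function(a, b) {
  da <- numeric(nrow(a)); db <- numeric(nrow(b))
  for (i in seq_len(nrow(a)))
    da[i] <- sqrt(min((a[i, 1L] - b[, 1L])^2 + (a[i, 2L] - b[, 2L])^2))
  for (j in seq_len(nrow(b)))
    db[j] <- sqrt(min((b[j, 1L] - a[, 1L])^2 + (b[j, 2L] - a[, 2L])^2))
  (mean(da) + mean(db)) / 2
}

# independent pairwise line-intersection accumulation: represent each
# (rho, theta) line by a point + direction and solve parametrically
bf_line_intersections <- function(lines, shape, min_angle = 3) {
  cnt <- matrix(0, shape[1L], shape[2L])
  n <- nrow(lines)
  if (n < 2L) return(cnt)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dth <- abs(lines$theta[i] - lines$theta[j])
    if (min(dth, 180 - dth) < min_angle) next
    t1 <- lines$theta[i] * pi / 180; t2 <- lines$theta[j] * pi / 180
    # point on line k: rho * (cos t, sin t); direction (-sin t, cos t)
    p1 <- lines$rho[i] * c(cos(t1), sin(t1)); d1 <- c(-sin(t1), cos(t1))
    p2 <- lines$rho[j] * c(cos(t2), sin(t2)); d2 <- c(-sin(t2), cos(t2))
    # solve p1 + s d1 = p2 + u d2 by Cramer
    det <- d1[1L] * (-d2[2L]) - (-d2[1L]) * d1[2L]
    rhs <- p2 - p1
    s <- (rhs[1L] * (-d2[2L]) - (-d2[1L]) * rhs[2L]) / det
    xy <- p1 + s * d1  # (x, y), 0-based
    r <- round(xy[2L]) + 1L; c <- round(xy[1L]) + 1L
    if (r >= 1L && r <= shape[1L] && c >= 1L && c <= shape[2L])
      cnt[r, c] <- cnt[r, c] + 1
  }
  cnt
}

# (rows, cols) raster of a filled disc
make_disc <- function(shape, center, radius, val = 1, bg = 0,
                      strict = FALSE) {
  d2 <- outer((seq_len(shape[1L]) - center[1L])^2,
              (seq_len(shape[2L]) - center[2L])^2, `+`)
  inside <- if (strict) d2 < radius^2 else d2 <= radius^2
  m <- matrix(bg, shape[1L], shape[2L])
  m[inside] <- val
  m
}

# ideal-disc crop window for segmentation recovery experiments: a bright
# disc at (window center + offset), radius disc_r, on dark background,
# with additive Gaussian noise
make_window <- function(side, disc_r, offset = c(0, 0), noise_sd = 0,
                        contrast = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  big <- 2L * side
  ctr <- c(big / 2 + 1, big / 2 + 1)
  img <- make_disc(c(big, big), ctr + offset, disc_r, val = contrast,
                   strict = TRUE)
  if (noise_sd > 0)
    img <- img + matrix(rnorm(big * big, 0, noise_sd), big, big)
  crop_window(img, ctr, side = side)
}
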