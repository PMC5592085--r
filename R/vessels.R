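# Vessel evidence: top-hat enhancement of the complemented green channel,
# a vessel-density map (difference of box means), a vessel-convergence map
# (Hough-line intersections of Canny edges), and the combined binary
# constraint mask that shrinks the search space for the disc detector.

#' Morphological top-hat vessel enhancement
#'
#' White top-hat (input minus grayscale opening) with a Euclidean disc of
#' radius 8 pixels, applied to the complemented green channel of the
#' 540-diameter frame. Vessels, being thinner than the structuring
#' element, survive; the slowly varying background is removed.
#'
#' Morphology uses clipped-neighbourhood (image-domain-restricted)
#' min/max. EBImage performs the erosion/dilation; since it clamps
#' grayscale values to [0,1], the input is affinely rescaled around the
#' operation (erosion and dilation commute with positive affine maps).
#'
#' @param g_c single-channel matrix (complemented green)
#' @param radius structuring-element radius in pixels (default 8)
#' @return nonnegative matrix, same shape
#' @export
enhance_vessels <- function(g_c, radius = 8) {
  rng <- range(g_c)
  if (rng[1] == rng[2]) return(matrix(0, nrow(g_c), ncol(g_c)))
  scaled <- (g_c - rng[1]) / (rng[2] - rng[1])
  kern <- disc_kernel(radius)
  opened <- EBImage::dilate(EBImage::erode(scaled, kern), kern)
  out <- (scaled - EBImage::imageData(opened)) * (rng[2] - rng[1])
  out[out < 0] <- 0  # guard FP round-off; top-hat is nonnegative
  out
}

#' Vessel density map
#'
#' Difference of two box means of the vessel-enhanced image: an 80 (rows)
#' x 40 (cols) mean minus an 80 x 120 mean. The narrow kernel responds to
#' the vertically elongated high-density vessel band through the disc,
#' the wide one to its horizontally flanking low-density background.
#' Negative values are clipped and the result is divided by its maximum
#' (all-zero input stays all-zero).
#'
#' @param v_e nonnegative matrix from [enhance_vessels()]
#' @param narrow,wide kernel sizes c(rows, cols)
#' @return matrix in [0, 1]
#' @export
vessel_density <- function(v_e, narrow = c(80, 40), wide = c(80, 120)) {
  d <- box_mean(v_e, narrow[1], narrow[2]) - box_mean(v_e, wide[1], wide[2])
  d[d < 0] <- 0
  mx <- max(d)
  if (mx > 0) d / mx else d
}

#' Canny edge detector
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding with the
#' low/high thresholds set at percentiles of the gradient-magnitude
#' distribution (inside the FOV when a mask is given). Hysteresis uses
#' 8-connectivity.
#'
#' @param m single-channel matrix
#' @param mask optional logical matrix restricting the percentile
#'   computation (e.g. the FOV)
#' @param sigma Gaussian smoothing sd in pixels
#' @param lo_q,hi_q hysteresis percentile levels in (0, 1)
#' @return logical matrix of edge pixels
#' @export
canny_edges <- function(m, mask = NULL, sigma = 1.4,
                        lo_q = 0.70, hi_q = 0.90) {
  nr <- nrow(m); nc <- ncol(m)
  g <- gaussian_blur(m, sigma)
  p <- pad_reflect(g, 1, 1, 1, 1)
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  gx <- (p[ri - 1, ci + 1] + 2 * p[ri, ci + 1] + p[ri + 1, ci + 1]) -
    (p[ri - 1, ci - 1] + 2 * p[ri, ci - 1] + p[ri + 1, ci - 1])
  gy <- (p[ri + 1, ci - 1] + 2 * p[ri + 1, ci] + p[ri + 1, ci + 1]) -
    (p[ri - 1, ci - 1] + 2 * p[ri - 1, ci] + p[ri - 1, ci + 1])
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nr, nc))

  # non-maximum suppression: compare each pixel with its two neighbours
  # along the quantized gradient direction
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                   ifelse(ang < 67.5, 1L, ifelse(ang < 112.5, 2L, 3L)))
  mp <- pad_reflect(mag, 1, 1, 1, 1)
  sh <- function(dr, dc) mp[ri + dr, ci + dc]
  n1 <- matrix(0, nr, nc); n2 <- n1
  # 0: horizontal gradient -> neighbours left/right
  # 1: 45 deg (gy, gx same sign quadrant) -> diag (+1,+1)/(-1,-1)
  # 2: vertical gradient -> up/down
  # 3: 135 deg -> diag (+1,-1)/(-1,+1)
  pick <- function(s, a, b) { n1[sector == s] <<- a[sector == s]
                              n2[sector == s] <<- b[sector == s] }
  pick(0L, sh(0, 1),  sh(0, -1))
  pick(1L, sh(1, 1),  sh(-1, -1))
  pick(2L, sh(1, 0),  sh(-1, 0))
  pick(3L, sh(1, -1), sh(-1, 1))
  nms <- mag
  nms[mag < n1 | mag < n2] <- 0

  pool <- if (is.null(mask)) mag else mag[mask]
  th <- stats::quantile(pool, c(lo_q, hi_q), names = FALSE, type = 7)
  if (th[2] <= 0) return(matrix(FALSE, nr, nc))
  strong <- nms > th[2]
  weak <- nms > th[1]
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- label8(weak)
  keep <- unique(lab[strong])
  weak & (lab %in% keep[keep > 0L])
}

#' 8-connected component labelling
#'
#' EBImage::bwlabel is 4-connected; diagonal-touching labels are merged
#' with a union-find pass.
#'
#' @param b logical matrix
#' @return integer matrix of labels (0 = background)
#' @keywords internal
label8 <- function(b) {
  lab <- EBImage::bwlabel(b * 1)
  nl <- max(lab)
  if (nl < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # (i,j) vs (i+1,j+1)
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # (i+1,j) vs (i,j+1)
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  matrix(c(0L, root)[lab + 1L], nr, nc)
}

#' Straight-line Hough transform peaks
#'
#' Accumulates edge pixels into a (rho, theta) accumulator (1 px x 1
#' degree bins, theta in 0..179) and extracts up to `k` peaks with a
#' minimum separation of `min_rho` bins in distance and `min_theta`
#' degrees in angle. Peaks weaker than `min_votes_frac` times the
#' strongest accumulator cell are discarded; 0.3 is the lowest floor
#' that still suppresses the aliased side lobes a single rasterized
#' line leaves in neighbouring angle bins (measured at up to 0.24 of
#' the main peak). Coordinates are 0-based (x = col - 1, y = row - 1),
#' rho = x cos(theta) + y sin(theta).
#'
#' @param edges logical matrix from [canny_edges()]
#' @param k maximum number of lines returned
#' @param min_rho,min_theta peak suppression radii (accumulator bins)
#' @param min_votes_frac minimum peak strength as a fraction of the
#'   accumulator maximum
#' @return data.frame with columns `rho`, `theta` (degrees), `votes`
#' @export
hough_lines <- function(edges, k = 30, min_rho = 5, min_theta = 5,
                        min_votes_frac = 0.3) {
  idx <- which(edges, arr.ind = TRUE)
  th <- (0:179) * pi / 180
  diag_len <- ceiling(sqrt(nrow(edges)^2 + ncol(edges)^2))
  n_rho <- 2L * diag_len + 1L
  if (nrow(idx) == 0L)
    return(data.frame(rho = numeric(0), theta = numeric(0),
                      votes = integer(0)))
  x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
  counts <- integer(n_rho * 180L)
  chunk <- 20000L
  for (s in seq(1L, length(x), by = chunk)) {
    e <- min(s + chunk - 1L, length(x))
    rho <- outer(x[s:e], cos(th)) + outer(y[s:e], sin(th))
    bin <- round(rho) + diag_len + 1L
    lin <- bin + rep(0L:179L, each = e - s + 1L) * n_rho
    tc <- tabulate(lin, nbins = n_rho * 180L)
    counts <- counts + tc
  }
  acc <- matrix(counts, n_rho, 180L)
  floor_votes <- min_votes_frac * max(acc)
  out <- matrix(0, 0L, 3L)
  for (i in seq_len(k)) {
    mx <- max(acc)
    if (mx <= 0 || mx < floor_votes) break
    w <- which(acc == mx, arr.ind = TRUE)
    w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE][1L, ]
    out <- rbind(out, c(w[1L] - diag_len - 1L, w[2L] - 1L, mx))
    rr <- pmax(1L, w[1L] - min_rho):pmin(n_rho, w[1L] + min_rho)
    tt <- ((w[2L] - 1L - min_theta):(w[2L] - 1L + min_theta)) %% 180L + 1L
    acc[rr, tt] <- 0
  }
  data.frame(rho = out[, 1L], theta = out[, 2L], votes = as.integer(out[, 3L]))
}

#' Pairwise Hough-line intersection accumulation
#'
#' For every unordered pair of lines whose angle difference is at least
#' `min_angle` degrees, adds 1 at the pixel nearest the intersection
#' point when it lies inside the frame.
#'
#' @param lines data.frame from [hough_lines()]
#' @param shape c(rows, cols) of the target frame
#' @param min_angle near-parallel cutoff in degrees
#' @return matrix of intersection counts
#' @export
line_intersections <- function(lines, shape, min_angle = 3) {
  cnt <- matrix(0, shape[1L], shape[2L])
  n <- nrow(lines)
  if (n < 2L) return(cnt)
  thr <- lines$theta * pi / 180
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dth <- abs(lines$theta[i] - lines$theta[j])
    dth <- min(dth, 180 - dth)
    if (dth < min_angle) next
    det <- sin(thr[j] - thr[i])
    x <- (lines$rho[i] * sin(thr[j]) - lines$rho[j] * sin(thr[i])) / det
    y <- (lines$rho[j] * cos(thr[i]) - lines$rho[i] * cos(thr[j])) / det
    r <- round(y) + 1L; c <- round(x) + 1L  # back to 1-based (row, col)
    if (r >= 1L && r <= shape[1L] && c >= 1L && c <= shape[2L])
      cnt[r, c] <- cnt[r, c] + 1
  }
  cnt
}

#' Vessel convergence map
#'
#' Canny edges of the vessel-enhanced image, straight-line Hough
#' transform, accumulation of pairwise line intersections, circular
#' averaging of radius 40, and division by the maximum. The value of
#' each pixel reflects the number of nearby Hough-line intersections;
#' vessels converge on the optic disc, so the map peaks there.
#'
#' @param v_e nonnegative matrix from [enhance_vessels()]
#' @param fov optional logical FOV mask (restricts Canny percentiles)
#' @param avg_radius radius of the circular averaging filter
#' @param hough_k number of Hough peak lines retained
#' @return matrix in [0, 1]
#' @export
vessel_convergence <- function(v_e, fov = NULL, avg_radius = 40,
                               hough_k = 30) {
  edges <- canny_edges(v_e, mask = fov)
  lines <- hough_lines(edges, k = hough_k)
  cnt <- line_intersections(lines, dim(v_e))
  v <- disc_mean(cnt, avg_radius)
  v[v < 0] <- 0
  mx <- max(v)
  if (mx > 0) v / mx else v
}

#' Threshold a max-normalized map
#'
#' Strict inequality: a pixel is kept iff its value exceeds the
#' threshold.
#'
#' @param m matrix in [0, 1]
#' @param threshold scalar in [0, 1]
#' @return logical matrix
#' @export
binarize_normalized <- function(m, threshold = 0.3) {
  stopifnot(threshold >= 0, threshold <= 1)
  m > threshold
}

#' Pixelwise conjunction of two binary masks
#'
#' @param a,b logical matrices of the same shape
#' @return logical matrix
#' @export
combine_masks <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  a & b
}

#' Full vessel-evidence bundle for a working image
#'
#' Computes the enhanced-vessel map and the density/convergence maps and
#' masks in one pass.
#'
#' @param w a `working_image`
#' @param config pipeline parameters from [od_config()]
#' @return list with elements `v_e`, `v_d`, `v_c`, `v_d_mask`,
#'   `v_c_mask`, `combined_mask`
#' @export
vessel_evidence <- function(w, config = od_config()) {
  g_c <- complement_green(w)
  v_e <- enhance_vessels(g_c, radius = config$tophat_radius)
  v_d <- vessel_density(v_e, narrow = config$density_kernel_narrow,
                        wide = config$density_kernel_wide)
  v_c <- vessel_convergence(v_e, fov = w$fov$mask,
                            avg_radius = config$convergence_avg_radius,
                            hough_k = config$hough_top_k)
  v_d_mask <- binarize_normalized(v_d, config$density_threshold)
  v_c_mask <- binarize_normalized(v_c, config$convergence_threshold)
  list(v_e = v_e, v_d = v_d, v_c = v_c,
       v_d_mask = v_d_mask, v_c_mask = v_c_mask,
       combined_mask = combine_masks(v_d_mask, v_c_mask))
}
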