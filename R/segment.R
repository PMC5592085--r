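# Optic disc segmentation: a circle of maximal ring contrast around the
# estimated center. The intensity image is cropped to a square window;
# concentric inner/outer ring pairs are scanned over a radius grid, in
# full or per half-plane sector, and the flexible four-sector model
# recombines the sector radii into a shifted circle.

#' Crop a square window around the estimated disc center
#'
#' Out-of-frame rows/columns are filled by edge replication.
#'
#' @param i intensity matrix (source frame)
#' @param center an `od_center`, or c(row, col) in the frame of `i`
#' @param side window side in pixels (even, >= 32)
#' @return object of class `crop_window`: list with `intensity`
#'   (side x side), `origin` c(row, col) of the window's first pixel in
#'   the source frame (1-based), `side`, `center_local` c(row, col)
#' @export
crop_window <- function(i, center, side = 140) {
  stopifnot(side %% 2 == 0, side >= 32)
  ctr <- if (inherits(center, "od_center"))
    c(center$row_norm, center$col_norm) else round(center)
  origin <- c(ctr[1L] - side / 2, ctr[2L] - side / 2)
  ri <- pmin(pmax(origin[1L] + seq_len(side) - 1L, 1L), nrow(i))
  ci <- pmin(pmax(origin[2L] + seq_len(side) - 1L, 1L), ncol(i))
  structure(list(intensity = i[ri, ci, drop = FALSE],
                 origin = origin, side = side,
                 center_local = c(side / 2 + 1, side / 2 + 1)),
            class = "crop_window")
}

# distance of every window pixel to the window center
.win_dist <- function(win) {
  d <- seq_len(win$side)
  dr <- d - win$center_local[1L]
  dc <- d - win$center_local[2L]
  sqrt(outer(dr^2, dc^2, `+`))
}

# logical half-plane selector for a sector
.sector_sel <- function(win, sector) {
  n <- win$side
  rsel <- switch(sector,
                 full  = rep(TRUE, n),
                 up    = seq_len(n) < win$center_local[1L],
                 down  = seq_len(n) >= win$center_local[1L],
                 rep(TRUE, n))
  csel <- switch(sector,
                 left  = seq_len(n) < win$center_local[2L],
                 right = seq_len(n) >= win$center_local[2L],
                 rep(TRUE, n))
  outer(rsel, csel, `&`)
}

#' Ring contrast measure CM(r)
#'
#' Mean intensity over the inner ring (r - thickness <= d < r) minus the
#' mean over the outer ring (r <= d < r + thickness), d the Euclidean
#' distance to the window center. At the true disc boundary the inner
#' ring lies on the bright disc and the outer on darker retina, so CM
#' peaks there.
#'
#' @param win a `crop_window`
#' @param r reference radius in pixels
#' @param thickness ring thickness in pixels (default 4% of the side)
#' @param sector one of "full", "up", "down", "left", "right"
#' @return scalar contrast
#' @export
contrast_measure <- function(win, r, thickness = 0.04 * win$side,
                             sector = "full") {
  d <- .win_dist(win)
  sel <- .sector_sel(win, sector)
  inner <- sel & d >= r - thickness & d < r
  outer_ <- sel & d >= r & d < r + thickness
  if (!any(inner) || !any(outer_)) stop("empty ring set at r = ", r)
  mean(win$intensity[inner]) - mean(win$intensity[outer_])
}

#' Scan the radius grid for the maximal-contrast circle
#'
#' Evaluates CM on the grid \{0.25, 0.26, ..., 0.45\} x side and returns
#' the radius attaining the maximum (ties broken toward the smallest
#' radius). For a sector other than "full" the ring pixel sets are
#' restricted to the corresponding half-plane.
#'
#' @param win a `crop_window`
#' @param sector one of "full", "up", "down", "left", "right"
#' @param grid_frac radius grid as fractions of the window side
#' @param thickness_frac ring thickness as a fraction of the side
#' @return list with `radius`, `cm_max`, and the full `profile`
#'   data.frame (radius, cm)
#' @export
scan_radii <- function(win, sector = "full",
                       grid_frac = seq(0.25, 0.45, by = 0.01),
                       thickness_frac = 0.04) {
  radii <- grid_frac * win$side
  thickness <- thickness_frac * win$side
  d <- .win_dist(win)
  sel <- .sector_sel(win, sector)
  ii <- win$intensity
  cm <- vapply(radii, function(r) {
    inner <- sel & d >= r - thickness & d < r
    outer_ <- sel & d >= r & d < r + thickness
    if (!any(inner) || !any(outer_)) return(-Inf)
    mean(ii[inner]) - mean(ii[outer_])
  }, numeric(1))
  best <- which(cm == max(cm))[1L]  # ties -> smallest radius (grid sorted)
  list(radius = radii[best], cm_max = cm[best],
       profile = data.frame(radius = radii, cm = cm))
}

#' Fit the flexible four-sector circle model
#'
#' Runs the radius scan independently in the up/down/left/right
#' half-planes. The final circle center is the window center shifted by
#' half the sector radius differences, ((r_down - r_up)/2, (r_right -
#' r_left)/2) in (row, col), and the final radius is the mean of the
#' four sector radii. When all four radii agree the fit reduces exactly
#' to the rigid full-circle fit.
#'
#' For a disc offset by d along one axis, the two sectors split by that
#' axis see edge distances rho - d and rho + d over a dense bundle of
#' directions, so their maximal-contrast radii move toward those
#' extremes and the half difference recovers d (exactly so once d
#' exceeds the ring thickness; smaller offsets are smoothed toward
#' (2/pi) d by the semicircle average). For oblique offsets both radius
#' differences also respond to the offset magnitude, so the recovered
#' center is direction-confounded; the half difference is the reading
#' of the sector geometry that keeps this confounding bounded.
#'
#' @param win a `crop_window`
#' @param grid_frac,thickness_frac see [scan_radii()]
#' @return object of class `circle_model`: list with `center` c(row,
#'   col) and `radius` in the source frame of the window, plus
#'   `sector_radii` (named r_up, r_down, r_left, r_right)
#' @export
fit_flexible_circle <- function(win, grid_frac = seq(0.25, 0.45, by = 0.01),
                                thickness_frac = 0.04) {
  r <- vapply(c("up", "down", "left", "right"), function(s)
    scan_radii(win, s, grid_frac, thickness_frac)$radius, numeric(1))
  names(r) <- c("r_up", "r_down", "r_left", "r_right")
  shift <- c((r[["r_down"]] - r[["r_up"]]) / 2,
             (r[["r_right"]] - r[["r_left"]]) / 2)
  center_local <- win$center_local + shift
  center_src <- win$origin + center_local - 1
  structure(list(center = unname(center_src), radius = unname(mean(r)),
                 sector_radii = r),
            class = "circle_model")
}

#' Rasterize a circle into a binary mask
#'
#' A pixel belongs to the mask iff the Euclidean distance from its
#' center to the circle center is at most the radius.
#'
#' @param circle a `circle_model`, or list with `center` and `radius`
#' @param shape c(rows, cols)
#' @return logical matrix
#' @export
rasterize_circle <- function(circle, shape) {
  stopifnot(all(shape >= 1))
  dr <- (seq_len(shape[1L]) - circle$center[1L])^2
  dc <- (seq_len(shape[2L]) - circle$center[2L])^2
  outer(dr, dc, `+`) <= circle$radius^2
}
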