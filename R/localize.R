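# Optic disc localization: a brightness detector (circular minus
# rectangular averaging of the vessel-compensated intensity image) whose
# argmax is taken inside the vessel-evidence constraint mask.

#' Intensity image
#'
#' Sum of the three RGB channels (range 0..765). The disc is usually the
#' brightest region of this image.
#'
#' @param x a `working_image` or (rows, cols, 3) array
#' @return nonnegative matrix
#' @export
intensity_image <- function(x) {
  a <- if (inherits(x, "working_image")) x$rgb else x
  a[, , 1L] + a[, , 2L] + a[, , 3L]
}

#' Vessel-compensated intensity image
#'
#' Vessel pixels inside the disc are dark in the intensity image; to
#' compensate, pixels whose vessel-enhanced value strictly exceeds its
#' 98.5th percentile are set to the maximum intensity. Both the
#' percentile and the maximum are computed over FOV pixels only when a
#' mask is supplied.
#'
#' @param i intensity matrix from [intensity_image()]
#' @param v_e vessel-enhanced matrix, same shape
#' @param fov optional logical FOV mask
#' @param percentile percentile level in percent (default 98.5)
#' @return matrix `I_c`
#' @export
vessel_overlay <- function(i, v_e, fov = NULL, percentile = 98.5) {
  stopifnot(all(dim(i) == dim(v_e)))
  sel <- if (is.null(fov)) rep(TRUE, length(i)) else as.vector(fov)
  thr <- stats::quantile(v_e[sel], percentile / 100, names = FALSE, type = 7)
  mx <- max(i[sel])
  out <- i
  repl <- (v_e > thr) & matrix(sel, nrow(i), ncol(i))
  out[repl] <- pmax(i[repl], mx)
  out
}

#' Optic disc brightness detector
#'
#' Circular averaging filter of radius 40 minus a rectangular 80 x 160
#' averaging filter, negatives clipped to zero. High where a disc-sized
#' bright blob is flanked horizontally by darker retina.
#'
#' @param i_c vessel-compensated intensity matrix
#' @param circle_radius radius of the circular mean
#' @param rect rectangular kernel c(rows, cols)
#' @return nonnegative matrix `D_OD`
#' @export
od_detector <- function(i_c, circle_radius = 40, rect = c(80, 160)) {
  d <- disc_mean(i_c, circle_radius) - box_mean(i_c, rect[1], rect[2])
  d[d < 0] <- 0
  d
}

#' Constrained argmax of the disc detector
#'
#' Returns the detector argmax over pixels where both the vessel
#' constraint mask and the FOV are set; if that intersection is empty the
#' argmax is taken over the FOV alone (`constrained = FALSE`). Ties are
#' broken by smallest row, then smallest column.
#'
#' @param d_od detector matrix
#' @param constraint logical constraint mask (`V_DC^b`)
#' @param fov `fov_mask` or logical matrix
#' @param scale normalized px per original px (for back-mapping)
#' @return object of class `od_center`: list with `row_norm`, `col_norm`
#'   (1-based, normalized frame), `row_orig`, `col_orig`,
#'   `detector_value`, `constrained`
#' @export
locate_od <- function(d_od, constraint, fov, scale = 1) {
  fmask <- if (inherits(fov, "fov_mask")) fov$mask else fov
  stopifnot(all(dim(d_od) == dim(fmask)))
  if (!any(fmask)) stop("empty FOV")
  sel <- constraint & fmask
  constrained <- any(sel)
  if (!constrained) {
    warning("vessel constraint mask empty inside FOV; ",
            "falling back to unconstrained argmax")
    sel <- fmask
  }
  v <- d_od
  v[!sel] <- -Inf
  mx <- max(v)
  cand <- which(v == mx, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE][1L, ]
  structure(list(row_norm = unname(cand[1L]), col_norm = unname(cand[2L]),
                 row_orig = unname(cand[1L]) / scale,
                 col_orig = unname(cand[2L]) / scale,
                 detector_value = mx, constrained = constrained),
            class = "od_center")
}

#' Locate the optic disc center in a fundus image
#'
#' Convenience wrapper running the full localization chain: FOV
#' detection, 540-px scale normalization, vessel evidence, vessel-
#' compensated brightness detector, constrained argmax.
#'
#' @param image file path or (rows, cols, 3) array (0..255)
#' @param config pipeline parameters from [od_config()]
#' @return an `od_center` (see [locate_od()]); attribute `working`
#'   carries the normalized `working_image` and vessel evidence for reuse
#' @export
od_locate <- function(image, config = od_config()) {
  rgb <- if (is.character(image)) read_fundus(image) else image
  w <- normalize_scale(rgb, target = config$retina_diameter)
  ev <- vessel_evidence(w, config)
  i <- intensity_image(w)
  i_c <- vessel_overlay(i, ev$v_e, fov = w$fov$mask,
                        percentile = config$vessel_percentile)
  d_od <- od_detector(i_c, circle_radius = config$detector_circle_radius,
                      rect = config$detector_rect)
  ctr <- locate_od(d_od, ev$combined_mask, w$fov, scale = w$scale)
  attr(ctr, "working") <- list(w = w, evidence = ev, intensity = i)
  ctr
}
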