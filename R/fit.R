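# The user-facing modelling interface: od_fit() runs the full
# localization + segmentation chain on one image and returns a classed
# object with the usual methods; od_batch() evaluates a set of images.

#' Pipeline configuration
#'
#' All method parameters with their defaults, valid for images
#' normalized to a 540-pixel retina diameter.
#'
#' @param tophat_radius structuring-element radius of the vessel top-hat
#' @param density_kernel_narrow,density_kernel_wide box kernels (rows,
#'   cols) of the vessel-density difference
#' @param density_threshold,convergence_threshold binarization
#'   thresholds on the max-normalized maps
#' @param convergence_avg_radius circular averaging radius of the
#'   convergence map
#' @param hough_top_k number of Hough peak lines retained
#' @param vessel_percentile vessel-overlay percentile (percent)
#' @param detector_circle_radius circular kernel radius of the disc
#'   detector
#' @param detector_rect rectangular kernel (rows, cols) of the disc
#'   detector
#' @param retina_diameter normalized retina diameter in pixels
#' @param crop_side segmentation window side in the normalized frame
#' @param radius_grid radius grid as fractions of the window side
#' @param ring_thickness ring thickness as a fraction of the window side
#' @return object of class `od_config` (a validated list)
#' @export
od_config <- function(tophat_radius = 8,
                      density_kernel_narrow = c(80, 40),
                      density_kernel_wide = c(80, 120),
                      density_threshold = 0.3,
                      convergence_threshold = 0.3,
                      convergence_avg_radius = 40,
                      hough_top_k = 30,
                      vessel_percentile = 98.5,
                      detector_circle_radius = 40,
                      detector_rect = c(80, 160),
                      retina_diameter = 540,
                      crop_side = 172,
                      radius_grid = seq(0.25, 0.45, by = 0.01),
                      ring_thickness = 0.04) {
  cfg <- list(tophat_radius = tophat_radius,
              density_kernel_narrow = density_kernel_narrow,
              density_kernel_wide = density_kernel_wide,
              density_threshold = density_threshold,
              convergence_threshold = convergence_threshold,
              convergence_avg_radius = convergence_avg_radius,
              hough_top_k = hough_top_k,
              vessel_percentile = vessel_percentile,
              detector_circle_radius = detector_circle_radius,
              detector_rect = detector_rect,
              retina_diameter = retina_diameter,
              crop_side = crop_side,
              radius_grid = radius_grid,
              ring_thickness = ring_thickness)
  stopifnot(density_threshold >= 0, density_threshold <= 1,
            convergence_threshold >= 0, convergence_threshold <= 1,
            all(unlist(cfg[c("tophat_radius", "density_kernel_narrow",
                             "density_kernel_wide", "convergence_avg_radius",
                             "detector_circle_radius", "detector_rect",
                             "retina_diameter", "crop_side")]) > 0),
            min(radius_grid) < max(radius_grid))
  structure(cfg, class = "od_config")
}

#' Write / read a flat key=value configuration file
#'
#' @param config an `od_config`
#' @param path file path
#' @return `read_od_config` returns an `od_config`
#' @export
write_od_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_od_config
#' @export
read_od_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(p) as.numeric(strsplit(trimws(p[2]), ",")[[1]])),
    vapply(kv, function(p) trimws(p[1]), character(1)))
  do.call(od_config, vals)
}

#' Fit the circular optic disc model to a fundus image
#'
#' Runs the full chain: FOV detection, normalization to the 540-px
#' retina-diameter frame, vessel evidence (top-hat, density,
#' Hough-convergence), the constrained brightness detector for the disc
#' center, and the flexible four-sector maximal-ring-contrast circle
#' fit. If a ground-truth mask is supplied the evaluation measures are
#' attached.
#'
#' @param image file path or (rows, cols, 3) array with values 0..255
#' @param truth optional ground-truth disc mask (path, binary matrix, or
#'   `ground_truth`), in original-image coordinates
#' @param config pipeline parameters from [od_config()]
#' @param keep_maps keep the intermediate maps in the returned object
#'   (for plotting/debugging; increases size)
#' @return object of class `od_fit` with components:
#'   \describe{
#'     \item{center}{`od_center` (normalized + original coordinates)}
#'     \item{circle}{`circle_model` in original-image coordinates}
#'     \item{circle_norm}{`circle_model` in the normalized frame}
#'     \item{sector_radii}{the four sector radii, normalized frame}
#'     \item{scale}{normalized px per original px}
#'     \item{metrics}{evaluation measures, if `truth` was given}
#'   }
#' @export
od_fit <- function(image, truth = NULL, config = od_config(),
                   keep_maps = FALSE) {
  rgb <- if (is.character(image)) read_fundus(image) else image
  ctr <- od_locate(rgb, config)
  wk <- attr(ctr, "working")
  win <- crop_window(wk$intensity, ctr, side = config$crop_side)
  circ_n <- fit_flexible_circle(win, grid_frac = config$radius_grid,
                                thickness_frac = config$ring_thickness)
  circ_o <- structure(list(center = circ_n$center / wk$w$scale,
                           radius = circ_n$radius / wk$w$scale,
                           sector_radii = circ_n$sector_radii / wk$w$scale),
                      class = "circle_model")
  fit <- structure(
    list(center = ctr, circle = circ_o, circle_norm = circ_n,
         sector_radii = circ_n$sector_radii, scale = wk$w$scale,
         original_shape = wk$w$original_shape, config = config,
         window = win, metrics = NULL),
    class = "od_fit")
  if (keep_maps) fit$maps <- wk$evidence
  if (!is.null(truth)) {
    gt <- if (inherits(truth, "ground_truth")) truth
    else if (is.character(truth)) ground_truth(read_mask(truth))
    else ground_truth(truth)
    pred <- rasterize_circle(circ_o, dim(gt$mask))
    fit$metrics <- od_metrics(c(ctr$row_orig, ctr$col_orig), pred, gt)
  }
  fit
}

#' @export
print.od_fit <- function(x, ...) {
  cat("Circular optic disc fit\n")
  cat(sprintf("  center (row, col): (%.1f, %.1f) px  [original frame]\n",
              x$circle$center[1L], x$circle$center[2L]))
  cat(sprintf("  radius: %.1f px\n", x$circle$radius))
  cat(sprintf("  scale: %.4f (normalized px / original px)\n", x$scale))
  cat(sprintf("  vessel-constrained localization: %s\n",
              x$center$constrained))
  if (!is.null(x$metrics))
    cat(sprintf("  vs truth: D* = %.3f, success = %s, JC = %.3f, DC = %.3f, MAD = %.2f px\n",
                x$metrics$d_star, x$metrics$success, x$metrics$jc,
                x$metrics$dc, x$metrics$mad))
  invisible(x)
}

#' @export
summary.od_fit <- function(object, ...) {
  print(object)
  sr <- object$sector_radii
  cat(sprintf("  sector radii (normalized frame): up %.1f, down %.1f, left %.1f, right %.1f px\n",
              sr[["r_up"]], sr[["r_down"]], sr[["r_left"]], sr[["r_right"]]))
  cat(sprintf("  detector value at center: %.2f\n",
              object$center$detector_value))
  invisible(object)
}

#' @export
coef.od_fit <- function(object, ...) {
  c(center_row = object$circle$center[1L],
    center_col = object$circle$center[2L],
    radius = object$circle$radius)
}

#' Predicted disc mask
#'
#' @param object an `od_fit`
#' @param shape output shape c(rows, cols); defaults to the original
#'   image shape
#' @param frame "original" or "normalized"
#' @param ... unused
#' @return logical matrix
#' @export
predict.od_fit <- function(object, shape = NULL,
                           frame = c("original", "normalized"), ...) {
  frame <- match.arg(frame)
  circ <- if (frame == "original") object$circle else object$circle_norm
  if (is.null(shape))
    shape <- if (frame == "original") object$original_shape
  else round(object$original_shape * object$scale)
  rasterize_circle(circ, shape)
}

#' Plot a fitted optic disc circle over the image
#'
#' @param x an `od_fit`
#' @param image the source image (path or array); required because fits
#'   do not retain the full image
#' @param ... passed to [graphics::plot()]
#' @export
plot.od_fit <- function(x, image, ...) {
  rgb <- if (is.character(image)) read_fundus(image) else image
  r <- grDevices::as.raster(rgb / 255)
  graphics::plot(c(1, ncol(rgb)), c(1, nrow(rgb)), type = "n", asp = 1,
                 xlab = "col", ylab = "row", ylim = c(nrow(rgb), 1), ...)
  graphics::rasterImage(r, 1, nrow(rgb), ncol(rgb), 1)
  th <- seq(0, 2 * pi, length.out = 256)
  graphics::lines(x$circle$center[2L] + x$circle$radius * cos(th),
                  x$circle$center[1L] + x$circle$radius * sin(th),
                  col = "green", lwd = 2)
  graphics::points(x$center$col_orig, x$center$row_orig, col = "yellow",
                   pch = 3, cex = 1.5)
  invisible(x)
}

#' Read / write a binary mask as 8-bit PNG (255 = inside)
#'
#' @param mask logical matrix
#' @param path file path
#' @return `read_mask` returns a logical matrix
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(t(mask * 1), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  d <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(d)) == 3L) d <- d[, , 1L]
  t(d) > 0.5
}

#' Batch evaluation over a set of images
#'
#' Runs [od_fit()] on each image (optionally with paired ground truth)
#' and aggregates the evaluation measures. The aggregate means equal
#' the arithmetic means of the per-image rows.
#'
#' @param images character vector of paths, or list of arrays /
#'   [synth_fundus()] results
#' @param truths optional parallel vector/list of ground truths; for
#'   `synth_fundus` results the embedded truth is used automatically
#' @param config pipeline parameters
#' @param csv,json optional output paths for the per-image table and the
#'   summary
#' @return list with `table` (data.frame: image, d_star, success, jc,
#'   dc, mad) and `summary` (means, success rate, JC-interval table)
#' @export
od_batch <- function(images, truths = NULL, config = od_config(),
                     csv = NULL, json = NULL) {
  if (length(images) == 0L) stop("no images supplied")
  n <- length(images)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    img <- images[[i]]
    tr <- if (!is.null(truths)) truths[[i]] else NULL
    if (is.list(img) && !is.null(img$rgb)) {  # synth_fundus result
      if (is.null(tr)) tr <- img$truth
      img <- img$rgb
    }
    name <- if (is.character(images[[i]])) basename(images[[i]])
    else sprintf("image_%03d", i)
    if (is.null(tr)) {
      fit <- od_fit(img, config = config)
      rows[[i]] <- data.frame(image = name, d_star = NA_real_,
                              success = NA, jc = NA_real_, dc = NA_real_,
                              mad = NA_real_)
    } else {
      fit <- od_fit(img, truth = tr, config = config)
      m <- fit$metrics
      rows[[i]] <- data.frame(image = name, d_star = m$d_star,
                              success = m$success, jc = m$jc, dc = m$dc,
                              mad = m$mad)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$jc)
  summ <- if (any(ok)) list(
    n = sum(ok),
    success_rate = mean(tab$success[ok]),
    mean_d_star = mean(tab$d_star[ok]),
    mean_jc = mean(tab$jc[ok]),
    mean_dc = mean(tab$dc[ok]),
    mean_mad = mean(tab$mad[ok]),
    jc_intervals = as.list(jc_interval_table(tab$jc[ok]))
  ) else list(n = 0L)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(summ, json, auto_unbox = TRUE, digits = NA)
  list(table = tab, summary = summ)
}
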