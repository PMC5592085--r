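# Evaluation measures: normalized center error D*, the center-inside-
# mask success criterion, Jaccard and Dice overlap, the symmetric mean
# average boundary distance (MAD), and the JC-interval summary table.

#' Ground-truth descriptor for a binary disc mask
#'
#' Computes the mask centroid (the reference center), the 4-connectivity
#' inner boundary (mask pixels with at least one 4-neighbour outside the
#' mask; frame borders count as outside), and the equivalent radius
#' R = sqrt(area / pi).
#'
#' @param mask logical matrix (TRUE = inside the disc)
#' @return object of class `ground_truth`: list with `mask`, `boundary`
#'   (n x 2 matrix of row, col), `center` c(row, col),
#'   `equivalent_radius`
#' @export
ground_truth <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty ground-truth mask")
  idx <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask,
                 boundary = boundary_pixels(mask),
                 center = c(mean(idx[, 1L]), mean(idx[, 2L])),
                 equivalent_radius = sqrt(sum(mask) / pi)),
            class = "ground_truth")
}

#' Inner boundary of a binary mask (4-connectivity)
#'
#' @param mask logical matrix
#' @return n x 2 integer matrix of (row, col) boundary pixels
#' @export
boundary_pixels <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  interior <- p[ri - 1L, ci] & p[ri + 1L, ci] & p[ri, ci - 1L] & p[ri, ci + 1L]
  which(mask & !interior, arr.ind = TRUE)
}

#' Normalized center error distance D*
#'
#' Euclidean distance between the estimated and true centers divided by
#' the radius of a circle whose area equals the ground-truth mask area.
#'
#' @param c_exp estimated center c(row, col)
#' @param gt a `ground_truth` (or binary mask)
#' @return nonnegative scalar
#' @export
normalized_error_distance <- function(c_exp, gt) {
  if (!inherits(gt, "ground_truth")) gt <- ground_truth(gt)
  sqrt(sum((c_exp - gt$center)^2)) / gt$equivalent_radius
}

#' Localization success criterion
#'
#' TRUE iff the estimated center, rounded to the nearest pixel, lies
#' inside the ground-truth mask (boundary pixels belong to the mask).
#'
#' @param c_exp estimated center c(row, col)
#' @param gt a `ground_truth` (or binary mask)
#' @return logical scalar
#' @export
od_success <- function(c_exp, gt) {
  if (!inherits(gt, "ground_truth")) gt <- ground_truth(gt)
  r <- round(c_exp[1L]); c <- round(c_exp[2L])
  if (r < 1 || c < 1 || r > nrow(gt$mask) || c > ncol(gt$mask)) return(FALSE)
  isTRUE(gt$mask[r, c])
}

#' Jaccard overlap coefficient
#'
#' @param s_od,s_truth binary matrices of the same shape
#' @return scalar in [0, 1]
#' @export
jaccard <- function(s_od, s_truth) {
  stopifnot(all(dim(s_od) == dim(s_truth)))
  a <- s_od > 0; b <- s_truth > 0
  u <- sum(a | b)
  if (u == 0) stop("both masks empty")
  sum(a & b) / u
}

#' Dice overlap coefficient
#'
#' @param s_od,s_truth binary matrices of the same shape
#' @return scalar in [0, 1]
#' @export
dice <- function(s_od, s_truth) {
  stopifnot(all(dim(s_od) == dim(s_truth)))
  a <- s_od > 0; b <- s_truth > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) stop("both masks empty")
  2 * sum(a & b) / denom
}

#' Mean average boundary distance (MAD)
#'
#' Symmetric mean of the two directed average nearest-neighbour
#' Euclidean distances between the boundary point sets.
#'
#' @param b_od,b_truth n x 2 matrices of (row, col) boundary points
#' @return nonnegative scalar (pixels)
#' @export
mean_average_distance <- function(b_od, b_truth) {
  if (NROW(b_od) == 0L || NROW(b_truth) == 0L) stop("empty boundary set")
  d2 <- outer(b_od[, 1L], b_truth[, 1L], `-`)^2 +
    outer(b_od[, 2L], b_truth[, 2L], `-`)^2
  dmin_a <- sqrt(apply(d2, 1L, min))
  dmin_b <- sqrt(apply(d2, 2L, min))
  (mean(dmin_a) + mean(dmin_b)) / 2
}

#' JC-interval summary table
#'
#' Fraction of reports whose Jaccard coefficient reaches each threshold.
#'
#' @param jc numeric vector of Jaccard values (or list of reports with a
#'   `jc` field)
#' @param thresholds decreasing thresholds
#' @return named numeric vector of fractions, non-increasing as the
#'   threshold rises
#' @export
jc_interval_table <- function(jc, thresholds = c(0.95, 0.90, 0.85,
                                                 0.80, 0.75, 0.70)) {
  if (is.list(jc)) jc <- vapply(jc, function(r) r$jc, numeric(1))
  if (length(jc) == 0L) stop("no reports")
  out <- vapply(thresholds, function(t) mean(jc >= t), numeric(1))
  names(out) <- paste0("JC>=", format(thresholds, nsmall = 2))
  out
}

#' Full metrics report for one segmentation against ground truth
#'
#' @param center estimated center c(row, col), same frame as the masks
#' @param mask_pred predicted binary mask
#' @param gt a `ground_truth` (or binary mask)
#' @return list with `d_star`, `success`, `jc`, `dc`, `mad`
#' @export
od_metrics <- function(center, mask_pred, gt) {
  if (!inherits(gt, "ground_truth")) gt <- ground_truth(gt)
  list(d_star = normalized_error_distance(center, gt),
       success = od_success(center, gt),
       jc = jaccard(mask_pred, gt$mask),
       dc = dice(mask_pred, gt$mask),
       mad = mean_average_distance(boundary_pixels(mask_pred), gt$boundary))
}
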