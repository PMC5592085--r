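# Seedable synthetic fundus generator with exact ground truth: a
# circular field of view on a dark surround, a bright sigmoid-rimmed
# disc, dark curved vessels converging on the disc center, an
# illumination gradient, optional exudate blobs, and Gaussian sensor
# noise. Every stage of the pipeline is testable against it without
# external image data.

#' Synthetic fundus specification
#'
#' Validates and bundles the generator parameters. Intensities are 8-bit
#' channel means; the disc must lie fully inside the field of view.
#'
#' @param frame image size c(rows, cols)
#' @param fov_radius FOV radius in pixels
#' @param fov_center FOV center c(row, col); defaults to the frame center
#' @param disc_center disc center c(row, col)
#' @param disc_radius disc radius in pixels
#' @param disc_intensity,background_intensity per-channel means (RGB,
#'   0..255)
#' @param rim_softness sigmoid edge scale of the disc rim, pixels
#' @param n_vessels number of vessels
#' @param vessel_width vessel stroke width, pixels
#' @param vessel_darkness fractional darkening of the green channel under
#'   a vessel (red/blue are darkened by half that)
#' @param n_exudates number of bright exudate blobs (placed at least 2
#'   disc radii from the disc center unless `exudate_near = TRUE`)
#' @param exudate_near place exudates adjacent to the disc (stress
#'   preset)
#' @param illumination_gradient fractional multiplicative ramp across
#'   the FOV
#' @param noise_sigma additive Gaussian noise sd, 8-bit units
#' @param seed RNG seed
#' @return object of class `synth_spec` (a validated list)
#' @export
synth_spec <- function(frame = c(600, 600), fov_radius = 270,
                       fov_center = frame / 2,
                       disc_center = c(300, 420), disc_radius = 54,
                       disc_intensity = c(235, 200, 130),
                       background_intensity = c(170, 80, 50),
                       rim_softness = 3,
                       n_vessels = 9, vessel_width = 4,
                       vessel_darkness = 0.55,
                       n_exudates = 0, exudate_near = FALSE,
                       illumination_gradient = 0.10,
                       noise_sigma = 5, seed = 1) {
  spec <- list(frame = frame, fov_radius = fov_radius,
               fov_center = fov_center, disc_center = disc_center,
               disc_radius = disc_radius, disc_intensity = disc_intensity,
               background_intensity = background_intensity,
               rim_softness = rim_softness, n_vessels = n_vessels,
               vessel_width = vessel_width,
               vessel_darkness = vessel_darkness,
               n_exudates = n_exudates, exudate_near = exudate_near,
               illumination_gradient = illumination_gradient,
               noise_sigma = noise_sigma, seed = seed)
  if (sqrt(sum((disc_center - fov_center)^2)) + disc_radius >= fov_radius)
    stop("disc not fully inside FOV")
  if (any(c(disc_intensity, background_intensity) < 0) ||
      any(c(disc_intensity, background_intensity) > 255))
    stop("intensities must be in [0, 255]")
  if (vessel_darkness < 0 || vessel_darkness > 1)
    stop("vessel_darkness must be a fraction in [0, 1]")
  structure(spec, class = "synth_spec")
}

# run expr with a locally seeded, portable RNG, restoring global state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# quadratic Bezier sampled densely enough for a connected stroke
.bezier <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

#' Generate a synthetic fundus image with exact ground truth
#'
#' Renders, in order: dark surround, reddish FOV disc with a
#' multiplicative illumination gradient, the bright optic disc with a
#' sigmoid rim, dark curved vessels (quadratic Beziers from near the
#' disc center to the FOV rim, darkest in green), optional exudates,
#' and additive Gaussian noise, clipped to 0..255. The ground truth is
#' the exact rasterized disc (distance <= disc_radius), before noise.
#'
#' @param spec a `synth_spec`
#' @return list with `rgb` (rows x cols x 3, 0..255), `truth` (a
#'   [ground_truth()]), `spec`
#' @export
synth_fundus <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  .with_seed(spec$seed, {
    nr <- spec$frame[1L]; nc <- spec$frame[2L]
    dr <- seq_len(nr) - spec$fov_center[1L]
    dc <- seq_len(nc) - spec$fov_center[2L]
    dist_fov <- sqrt(outer(dr^2, dc^2, `+`))
    fov <- dist_fov <= spec$fov_radius

    ddr <- seq_len(nr) - spec$disc_center[1L]
    ddc <- seq_len(nc) - spec$disc_center[2L]
    dist_disc <- sqrt(outer(ddr^2, ddc^2, `+`))
    # sigmoid rim profile: 1 well inside the disc, 0 well outside
    disc_w <- 1 / (1 + exp((dist_disc - spec$disc_radius) / spec$rim_softness))

    # illumination: multiplicative linear ramp in a random direction
    phi <- stats::runif(1, 0, 2 * pi)
    ramp <- 1 + spec$illumination_gradient *
      (outer(dr * sin(phi), dc * cos(phi), `+`) / spec$fov_radius)

    # vessels: each passes within 0.2 disc radii of the disc center and
    # extends to the FOV rim
    vmask <- matrix(FALSE, nr, nc)
    vessel_paths <- vector("list", spec$n_vessels)
    if (spec$n_vessels > 0) {
      ang <- stats::runif(spec$n_vessels, 0, 2 * pi)
      for (v in seq_len(spec$n_vessels)) {
        a0 <- stats::runif(1, 0, 2 * pi)
        rad0 <- stats::runif(1, 0, 0.2 * spec$disc_radius)
        p0 <- spec$disc_center + rad0 * c(sin(a0), cos(a0))
        p2 <- spec$fov_center + (spec$fov_radius - 1) *
          c(sin(ang[v]), cos(ang[v]))
        mid <- (p0 + p2) / 2
        perp <- c(-(p2 - p0)[2L], (p2 - p0)[1L])
        perp <- perp / sqrt(sum(perp^2))
        bow <- stats::runif(1, -0.12, 0.12) * sqrt(sum((p2 - p0)^2))
        p1 <- mid + bow * perp
        n_s <- max(50L, ceiling(2 * sqrt(sum((p2 - p0)^2))))
        pts <- .bezier(p0, p1, p2, n_s)
        vessel_paths[[v]] <- pts
        pr <- pmin(pmax(round(pts[, 1L]), 1L), nr)
        pc <- pmin(pmax(round(pts[, 2L]), 1L), nc)
        vmask[cbind(pr, pc)] <- TRUE
      }
      halfw <- max(1L, floor(spec$vessel_width / 2))
      vmask <- EBImage::imageData(
        EBImage::dilate(vmask * 1, disc_kernel(halfw))) > 0
      vmask <- vmask & fov
    }

    # exudates: small bright blobs with a soft profile
    ex_centers <- NULL
    if (spec$n_exudates > 0) {
      lo <- if (spec$exudate_near) 1.1 else 2.0
      hi <- if (spec$exudate_near) 1.6 else 3.5
      k <- 0L
      while (k < spec$n_exudates) {
        d_off <- stats::runif(1, lo, hi) * spec$disc_radius
        a <- stats::runif(1, 0, 2 * pi)
        ctr <- spec$disc_center + d_off * c(sin(a), cos(a))
        if (sqrt(sum((ctr - spec$fov_center)^2)) < spec$fov_radius - 12) {
          ex_centers <- rbind(ex_centers,
                              c(ctr, stats::runif(1, 3, 7)))
          k <- k + 1L
        }
      }
    }

    rgb <- array(0, c(nr, nc, 3L))
    vfac <- c(1 - spec$vessel_darkness / 2, 1 - spec$vessel_darkness,
              1 - spec$vessel_darkness / 2)
    for (ch in 1:3) {
      base <- spec$background_intensity[ch] * ramp
      layer <- base * (1 - disc_w) + spec$disc_intensity[ch] * disc_w
      layer[vmask] <- layer[vmask] * vfac[ch]
      if (!is.null(ex_centers)) for (e in seq_len(nrow(ex_centers))) {
        de <- sqrt(outer((seq_len(nr) - ex_centers[e, 1L])^2,
                         (seq_len(nc) - ex_centers[e, 2L])^2, `+`))
        wgt <- exp(-(de / ex_centers[e, 3L])^2)
        layer <- layer + (spec$disc_intensity[ch] - base) * pmin(wgt, 1)
      }
      layer[!fov] <- 0
      if (spec$noise_sigma > 0)
        layer <- layer + matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma),
                                nr, nc)
      layer[layer < 0] <- 0
      layer[layer > 255] <- 255
      layer[!fov] <- 0
      rgb[, , ch] <- layer
    }

    res <- list(rgb = rgb, truth = ground_truth(dist_disc <= spec$disc_radius),
                spec = spec)
    attr(res, "vessel_paths") <- vessel_paths
    res
  })
}

#' Default synthetic test battery
#'
#' Draws `n` specifications with randomized disc position (anywhere in
#' the nasal half of the FOV), disc radius uniform in 8-12% of the FOV
#' diameter, 6-12 vessels and noise sd 4-8, all deterministic given the
#' master seed.
#'
#' @param n number of images
#' @param master_seed seed for the battery-level draws (each image also
#'   receives its own derived seed)
#' @param noise_sigma optional fixed noise sd overriding the 4-8 draw
#'   (used by the noise-degradation study)
#' @return list of `n` results from [synth_fundus()]
#' @export
synth_battery <- function(n = 50, master_seed = 0, noise_sigma = NULL) {
  stopifnot(n >= 1)
  specs <- .with_seed(master_seed, {
    lapply(seq_len(n), function(i) {
      fov_r <- 270
      fov_c <- c(300, 300)
      disc_r <- stats::runif(1, 0.08, 0.12) * 2 * fov_r
      side <- sample(c(-1, 1), 1)  # which half is nasal depends on the eye
      max_off <- fov_r - disc_r - 15
      col_off <- side * stats::runif(1, 0.25, min(0.55, max_off / fov_r)) * fov_r
      row_off <- stats::runif(1, -0.25, 0.25) * fov_r
      # keep the disc well inside the FOV
      off <- c(row_off, col_off)
      if (sqrt(sum(off^2)) > max_off) off <- off * max_off / sqrt(sum(off^2))
      synth_spec(frame = c(600, 600), fov_radius = fov_r, fov_center = fov_c,
                 disc_center = fov_c + off, disc_radius = disc_r,
                 n_vessels = sample(6:12, 1),
                 noise_sigma = if (is.null(noise_sigma))
                   stats::runif(1, 4, 8) else noise_sigma,
                 seed = sample.int(.Machine$integer.max, 1))
    })
  })
  lapply(specs, synth_fundus)
}
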