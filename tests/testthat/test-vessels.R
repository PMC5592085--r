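test_that("top-hat removes constants and keeps sub-element peaks", {
  expect_equal(enhance_vessels(matrix(42, 40, 40)), matrix(0, 40, 40))

  m <- matrix(0, 41, 41); m[21, 21] <- 100
  th <- enhance_vessels(m)
  expect_equal(th[21, 21], 100)
  expect_equal(sum(th) - th[21, 21], 0)
})

test_that("top-hat response vanishes deep inside a large plateau", {
  m <- matrix(0, 80, 80)
  m[16:65, 16:65] <- 100  # 50x50 square
  th <- enhance_vessels(m)
  # interior points at least 8 px from the square edge
  expect_equal(max(abs(th[24:57, 24:57])), 0)
  expect_equal(th, bf_tophat(m, 8), tolerance = 1e-9)
})

test_that("top-hat is invariant to additive offsets", {
  set.seed(5)
  m <- matrix(runif(50 * 50, 0, 200), 50, 50)
  expect_equal(enhance_vessels(m), enhance_vessels(m + 37.5),
               tolerance = 1e-9)
})

test_that("vessel density peaks on a vertical strip and guards zero input", {
  z <- matrix(0, 50, 60)
  expect_equal(vessel_density(z), z)

  # tall frame, vertical strip of width 20: narrow mean 20/40, wide mean
  # 20/120, raw difference 1/3 is the map's maximum -> normalized 1
  m <- matrix(0, 400, 200)
  m[, 91:110] <- 1
  vd <- vessel_density(m)
  expect_equal(vd[200, 100], 1, tolerance = 1e-9)
  raw <- box_mean(m, 80, 40) - box_mean(m, 80, 120)
  expect_equal(raw[200, 100], 20 / 40 - 20 / 120, tolerance = 1e-9)

  # constant input: equal means everywhere (reflect padding), all zero
  expect_equal(vessel_density(matrix(3, 100, 100)),
               matrix(0, 100, 100), tolerance = 1e-9)
})

test_that("density and convergence maps stay within [0, 1]", {
  set.seed(8)
  for (i in 1:3) {
    m <- matrix(runif(120 * 120, 0, 50), 120, 120)
    vd <- vessel_density(m)
    expect_gte(min(vd), 0); expect_lte(max(vd), 1)
    vc <- vessel_convergence(m, avg_radius = 10)
    expect_gte(min(vc), 0); expect_lte(max(vc), 1)
  }
})

strip_image <- function(shape, center, angle, width = 5, val = 100) {
  # bright straight strip through `center` at `angle` (radians)
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d <- abs((c - center[2]) * sin(angle) - (r - center[1]) * cos(angle))
  m <- matrix(0, shape[1], shape[2])
  m[d <= width / 2] <- val
  m
}

test_that("convergence localizes the crossing of two strips", {
  p <- c(110, 130)
  m <- strip_image(c(240, 240), p, 0.3) + strip_image(c(240, 240), p, 1.9)
  vc <- vessel_convergence(m)
  am <- which(vc == max(vc), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((am - p)^2)), 40)
})

test_that("convergence is zero without crossing lines", {
  one <- strip_image(c(200, 200), c(100, 100), 0.7)
  expect_equal(max(vessel_convergence(one)), 0)
  two <- strip_image(c(200, 200), c(60, 100), 0) +
    strip_image(c(200, 200), c(140, 100), 0)
  expect_equal(max(vessel_convergence(two)), 0)
})

test_that("binarization uses a strict inequality", {
  m <- matrix(c(0.31, 0.30, 0.29, 1), 2, 2)
  b <- binarize_normalized(m, 0.3)
  expect_identical(as.vector(b), c(TRUE, FALSE, FALSE, TRUE))
  expect_false(any(binarize_normalized(matrix(0.3, 3, 3), 0.3)))
})

test_that("mask conjunction is idempotent, commutative and exact", {
  a <- make_disc(c(60, 60), c(28, 25), 15) > 0
  b <- make_disc(c(60, 60), c(35, 38), 18) > 0
  expect_identical(combine_masks(a, a), a)
  expect_false(any(combine_masks(a, matrix(FALSE, 60, 60))))
  expect_identical(combine_masks(a, b), combine_masks(b, a))
  c3 <- make_disc(c(60, 60), c(30, 30), 20) > 0
  expect_identical(combine_masks(combine_masks(a, b), c3),
                   combine_masks(a, combine_masks(b, c3)))
  # set-intersection oracle over pixel coordinate sets
  inter <- combine_masks(a, b)
  set_a <- which(a); set_b <- which(b)
  expect_identical(sort(which(inter)), sort(intersect(set_a, set_b)))
  expect_error(combine_masks(a, matrix(TRUE, 10, 10)), "shape")
})

test_that("the combined constraint mask covers the disc center region", {
  b <- synth_battery(6, master_seed = 11)
  for (s in b) {
    w <- normalize_scale(s$rgb)
    ev <- vessel_evidence(w)
    expect_true(any(ev$combined_mask & w$fov$mask))
    ctr <- s$spec$disc_center * w$scale
    idx <- which(ev$combined_mask, arr.ind = TRUE)
    d <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
    expect_lte(min(d), 0.5 * s$spec$disc_radius * w$scale)
  }
})

test_that("hough transform recovers a drawn line's parameters", {
  m <- strip_image(c(150, 150), c(75, 75), 0.5, width = 3)
  edges <- canny_edges(m)
  ln <- hough_lines(edges, k = 5)
  expect_gt(nrow(ln), 0)
  # the strip runs at angle 0.5 from vertical in (row, col); its normal
  # direction in (x, y) = (col, row) coordinates is theta = 180 - deg(0.5)
  # or its complement; accept either representative
  best <- ln[1, ]
  ang <- best$theta
  expect_true(min(abs(ang - 61.4), abs(ang - 118.6), abs(180 - ang - 61.4)) < 8)
})

test_that("line intersection accumulation matches the independent solver", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 8
    lines <- data.frame(rho = runif(n, -40, 80),
                        theta = sample(0:179, n), votes = 1L)
    got <- line_intersections(lines, c(64, 64))
    want <- bf_line_intersections(lines, c(64, 64))
    expect_identical(got, want)
  }
})
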