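test_that("crop window copies interior pixels and replicates edges", {
  set.seed(4)
  img <- matrix(runif(300 * 300), 300, 300)
  win <- crop_window(img, c(150, 150), side = 40)
  expect_equal(win$origin, c(130, 130))
  expect_equal(win$center_local, c(21, 21))
  expect_equal(win$intensity, img[130:169, 130:169])

  # center near the top edge: missing rows replicate the first image row
  win2 <- crop_window(img, c(11, 150), side = 140)
  expect_equal(win2$origin, c(11 - 70, 150 - 70))
  for (k in 1:60) expect_equal(win2$intensity[k, ], img[1, 80:219])
  expect_equal(win2$intensity[61, ], img[1, 80:219])
  expect_equal(win2$intensity[62, ], img[2, 80:219])
})

test_that("ring contrast is 1 across an ideal edge and 0 inside", {
  side <- 100; r0 <- 32
  big <- matrix(0, 200, 200)
  big[make_disc(c(200, 200), c(101, 101), r0, strict = TRUE) > 0] <- 1
  win <- crop_window(big, c(101, 101), side = side)
  expect_equal(contrast_measure(win, r0), 1)
  expect_equal(contrast_measure(win, r0 / 2, thickness = 3), 0)
})

test_that("ring contrast is shift invariant and scales linearly", {
  win <- make_window(100, 30, noise_sd = 2, seed = 42)
  cm <- contrast_measure(win, 28)
  win_b <- win; win_b$intensity <- win$intensity + 55.5
  expect_equal(contrast_measure(win_b, 28), cm, tolerance = 1e-9)
  win_c <- win; win_c$intensity <- win$intensity * 3.25
  expect_equal(contrast_measure(win_c, 28), 3.25 * cm, tolerance = 1e-9)
})

test_that("radius scan recovers an ideal centered disc on the grid", {
  side <- 160
  r0 <- 0.35 * side
  win <- make_window(side, r0)
  full <- scan_radii(win)
  expect_lte(abs(full$radius - r0), 0.01 * side)
  for (s in c("up", "down", "left", "right"))
    expect_equal(scan_radii(win, s)$radius, full$radius)
})

test_that("radius scan ties break to the smallest grid radius", {
  win <- make_window(120, 30)
  win$intensity[] <- 7  # uniform: CM = 0 at every radius
  expect_equal(scan_radii(win)$radius, 0.25 * 120)
})

test_that("flexible fit recovers an off-center disc via sector radii", {
  side <- 160
  r0 <- 0.33 * side
  step <- 0.01 * side
  win <- make_window(side, r0, offset = c(0, 5))
  fit <- fit_flexible_circle(win)
  sr <- fit$sector_radii
  # for an offset smaller than the ring thickness the semicircle ring
  # smooths the edge offset d*cos(theta) toward its half-plane average,
  # so each sector radius moves by about (2/pi)*d rather than d
  expect_lte(abs(sr[["r_right"]] - (r0 + 2 / pi * 5)), step)
  expect_lte(abs(sr[["r_left"]] - (r0 - 2 / pi * 5)), step)
  expect_lte(abs((sr[["r_right"]] - sr[["r_left"]]) - 4 / pi * 5), step)
  # the recovered center accordingly under-corrects by the same factor:
  # allow two grid steps for |(2/pi - 1)| * 5 px plus quantization
  true_ctr <- win$origin + win$center_local - 1 + c(0, 5)
  expect_lte(max(abs(fit$center - true_ctr)), 2 * step)
  expect_lte(abs(fit$radius - r0), step)
})

test_that("flexible fit degenerates to the rigid fit when centered", {
  side <- 160
  win <- make_window(side, 0.35 * side)
  fit <- fit_flexible_circle(win)
  rigid <- scan_radii(win, "full")
  expect_equal(unname(fit$sector_radii), rep(rigid$radius, 4))
  expect_equal(fit$radius, rigid$radius)
  expect_equal(fit$center, win$origin + win$center_local - 1)
})

test_that("rasterized circles have the right support", {
  one <- rasterize_circle(list(center = c(5, 7), radius = 0.4), c(12, 12))
  expect_equal(sum(one), 1)
  expect_true(one[5, 7])

  big <- rasterize_circle(list(center = c(101, 101), radius = 50), c(201, 201))
  expect_lt(abs(sum(big) - pi * 50^2) / (pi * 50^2), 0.01)
  # reflection symmetry through the center row and column
  expect_identical(big, big[201:1, ])
  expect_identical(big, big[, 201:1])
})
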