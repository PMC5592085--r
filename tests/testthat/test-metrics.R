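test_that("normalized error distance scales by the equivalent radius", {
  gt <- ground_truth(make_disc(c(200, 200), c(100, 100), 50) > 0)
  expect_equal(normalized_error_distance(gt$center, gt), 0)

  # offset 25 px on a radius-50 disc: D* ~ 25 / sqrt(A / pi) ~ 0.5
  a <- sum(gt$mask)  # brute-force pixel count
  expect_equal(normalized_error_distance(gt$center + c(0, 25), gt),
               25 / sqrt(a / pi), tolerance = 1e-12)
  expect_lt(abs(normalized_error_distance(gt$center + c(0, 25), gt) - 0.5),
            0.01)
  # doubling the offset doubles D* exactly
  d1 <- normalized_error_distance(gt$center + c(3, 4), gt)
  d2 <- normalized_error_distance(gt$center + c(6, 8), gt)
  expect_equal(d2, 2 * d1)
  expect_error(ground_truth(matrix(FALSE, 5, 5)), "empty")
})

test_that("success means the rounded center lies on the mask", {
  mask <- make_disc(c(60, 60), c(30, 30), 10) > 0
  gt <- ground_truth(mask)
  expect_true(od_success(c(30, 30), gt))
  expect_false(od_success(c(30, 41.4), gt))  # 1 px outside
  # boundary pixels belong to the mask
  b <- gt$boundary[1, ]
  expect_true(od_success(as.numeric(b), gt))
})

test_that("jaccard and dice follow the overlap arithmetic", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(jaccard(a, a), 1)
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(jaccard(a, b), 0)
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100, overlap 50
  c2 <- matrix(FALSE, 20, 20); c2[1:10, 6:15] <- TRUE
  expect_equal(jaccard(a, c2), 1 / 3)
  expect_equal(dice(a, c2), 0.5)
  expect_equal(dice(a, c2), 2 * (1 / 3) / (1 + 1 / 3))
  expect_error(jaccard(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), "empty")
})

test_that("boundary distance matches the all-pairs oracle", {
  m1 <- make_disc(c(80, 80), c(40, 40), 10) > 0
  expect_equal(mean_average_distance(boundary_pixels(m1),
                                     boundary_pixels(m1)), 0)

  p1 <- matrix(c(10, 10), 1); p2 <- matrix(c(10, 15), 1)
  expect_equal(mean_average_distance(p1, p2), 5)

  # concentric circles radii 10 and 20: boundary separation ~ 10
  b10 <- boundary_pixels(make_disc(c(80, 80), c(40, 40), 10) > 0)
  b20 <- boundary_pixels(make_disc(c(80, 80), c(40, 40), 20) > 0)
  mad <- mean_average_distance(b10, b20)
  expect_lt(abs(mad - 10), 0.5)
  expect_equal(mad, bf_mad(b10, b20))
  # symmetry
  expect_equal(mean_average_distance(b20, b10), mad)
})

test_that("metric identities hold on random mask pairs", {
  set.seed(17)
  for (i in 1:25) {
    a <- make_disc(c(50, 50), runif(2, 15, 35), runif(1, 5, 14)) > 0
    b <- make_disc(c(50, 50), runif(2, 15, 35), runif(1, 5, 14)) > 0
    if (!any(a | b)) next
    jc <- jaccard(a, b); dc <- dice(a, b)
    expect_equal(dc, 2 * jc / (1 + jc), tolerance = 1e-12)
    expect_true(jc >= 0 && jc <= 1 && dc >= 0 && dc <= 1)
    expect_lte(jc, dc)
    expect_equal(jaccard(b, a), jc)
  }
})

test_that("JC interval table counts nested events", {
  expect_equal(unname(jc_interval_table(rep(1, 4))), rep(1, 6))
  tab <- jc_interval_table(c(0.96, 0.91, 0.72))
  expect_equal(unname(tab), c(1, 2, 2, 2, 2, 3) / 3)
  expect_true(all(diff(unname(tab)) >= 0))  # thresholds listed descending
  set.seed(1)
  rnd <- jc_interval_table(runif(40))
  expect_true(all(diff(unname(rnd)) >= 0))
})

test_that("od_metrics bundles all measures consistently", {
  truth <- make_disc(c(120, 120), c(60, 60), 25) > 0
  pred <- rasterize_circle(list(center = c(62, 61), radius = 24), c(120, 120))
  m <- od_metrics(c(62, 61), pred, truth)
  expect_true(m$success)
  expect_equal(m$dc, 2 * m$jc / (1 + m$jc), tolerance = 1e-12)
  expect_equal(m$d_star,
               normalized_error_distance(c(62, 61), ground_truth(truth)))
  expect_gt(m$jc, 0.8)
  expect_lt(m$mad, 4)
})
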