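test_that("maximum projection is the pixel-wise maximum", {
  arr <- array(0, c(2, 2, 2))
  arr[1, , ] <- matrix(c(0, 2, 1, 0), 2, 2)  # column-major
  arr[2, , ] <- matrix(c(2, 0, 0, 3), 2, 2)
  st <- image_stack(arr, pixel_size = 0.5)
  expect_equal(max_project(st), matrix(c(2, 2, 1, 3), 2, 2))
  # single-slice range is the identity
  expect_equal(max_project(st, 1), arr[1, , ])
  # projection dominates every included slice
  rnd <- image_stack(array(abs(sin(1:250)), c(5, 5, 10)), pixel_size = 1)
  pr <- max_project(rnd, 2:4)
  for (z in 2:4) expect_true(all(pr >= rnd$data[z, , ]))
  expect_error(max_project(st, integer(0)), "empty")
  expect_error(max_project(st, 3), "within")
})

test_that("max projection is idempotent and commutes with monotone rescaling", {
  arr <- array(abs(sin(1:75)), c(3, 5, 5))
  st <- image_stack(arr, pixel_size = 1)
  p <- max_project(st)
  expect_equal(max_project(image_stack(p, 1)), p)
  g <- function(v) sqrt(v) + 2 * v          # monotone increasing
  expect_equal(max_project(image_stack(g(arr), 1)), g(p), tolerance = 1e-12)
})

test_that("linescan sampling interpolates bilinearly in physical units", {
  img <- matrix(7, 20, 20)
  prof <- extract_linescan(img, c(0.3, 0.2), c(1.7, 1.9), pixel_size = 0.1)
  expect_true(all(abs(prof$intensities - 7) < 1e-12))
  # axis-aligned line through pixel centres returns the pixel values
  img2 <- matrix(seq_len(100), 10, 10)  # value = row + 10*(col-1)
  prof2 <- extract_linescan(img2, c(0, 0.2), c(0.9, 0.2), pixel_size = 0.1,
                            sampling_step = 0.1)
  expect_equal(prof2$intensities, img2[3, ], tolerance = 1e-12)
  # midpoint between two pixel centres averages them
  prof3 <- extract_linescan(img2, c(0.05, 0.2), c(0.85, 0.2), pixel_size = 0.1,
                            sampling_step = 0.1)
  expect_equal(prof3$intensities[1], mean(img2[3, 1:2]), tolerance = 1e-12)
  expect_error(extract_linescan(img, c(0, 0), c(5, 0), pixel_size = 0.1),
               "within the image")
  expect_error(extract_linescan(img, c(0, 0), c(0, 0), pixel_size = 0.1),
               "differ")
})

test_that("a 20 um line sampled at pixel pitch yields 20/pixel_size + 1 samples", {
  epi <- synth_epithelium_image(n_cells = 36L, cell_size = 5, pixel_size = 0.1,
                                seed = 9L)
  img <- max_project(epi$stack)
  ps <- epi$stack$pixel_size
  prof <- extract_linescan(img, c(1, 10), c(21, 10), pixel_size = ps,
                           sampling_step = ps)
  expect_length(prof$intensities, 20 / ps + 1)
  expect_equal(max(prof$positions), 20, tolerance = 1e-9)
})

test_that("heterogeneity is sd/mean with the sample denominator", {
  h <- linescan_stats(c(1, 2, 3, 4))
  expect_equal(h$mean_intensity, 2.5)
  expect_equal(h$sd_intensity, sqrt(sum((c(1, 2, 3, 4) - 2.5)^2) / 3),
               tolerance = 1e-12)
  expect_equal(h$heterogeneity, 0.5163978, tolerance = 1e-6)
  expect_equal(linescan_stats(rep(3, 8))$heterogeneity, 0)
  # population-denominator switch
  hn <- linescan_stats(c(1, 2, 3, 4), sd_denominator = "n")
  expect_equal(hn$sd_intensity, sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)),
               tolerance = 1e-12)
  expect_error(linescan_stats(c(-2, -1, 0)), "positive")
})

test_that("heterogeneity is scale-invariant and increases under modulation", {
  base <- abs(sin(1:50)) + 1
  h0 <- linescan_stats(base)$heterogeneity
  for (c_ in c(0.01, 3, 1e4)) {
    expect_equal(linescan_stats(c_ * base)$heterogeneity, h0, tolerance = 1e-12)
  }
  flat <- rep(10, 60)
  mod <- flat * (1 + 0.3 * sin(2 * pi * seq_along(flat) / 10))
  expect_gt(linescan_stats(mod)$heterogeneity, linescan_stats(flat)$heterogeneity)
})

test_that("per-embryo summaries reduce linescans to condition rows", {
  p_const <- rep(5, 30)
  s1 <- condition_linescan_summary(list(embryoA = p_const))
  expect_equal(s1$mean_intensity, 5)
  expect_equal(s1$heterogeneity, 0)
  expect_equal(s1$n_linescans, 1L)
  # identical embryos give identical rows
  s2 <- condition_linescan_summary(list(a = p_const, b = p_const))
  expect_equal(s2$mean_intensity[1], s2$mean_intensity[2])
  expect_equal(s2$heterogeneity[1], s2$heterogeneity[2])
  # several linescans per embryo are averaged and counted
  s3 <- condition_linescan_summary(list(a = list(p_const, p_const * 2)))
  expect_equal(s3$n_linescans, 2L)
  expect_equal(s3$mean_intensity, mean(c(5, 10)))
})
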