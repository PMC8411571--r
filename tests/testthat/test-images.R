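square_roi <- function(x0, y0, side) {
  cbind(x = c(x0, x0 + side, x0 + side, x0),
        y = c(y0, y0, y0 + side, y0 + side))
}

test_that("polygon rasterization matches a pracma point-in-polygon oracle", {
  skip_if_not_installed("pracma")
  withr::with_seed(401, {
    for (rep in 1:8) {
      # random convex polygon (vertices on a jittered circle, angle-sorted)
      k <- sample(3:8, 1)
      ang <- sort(stats::runif(k, 0, 2 * pi))
      r <- stats::runif(1, 8, 20)
      cx <- stats::runif(1, 25, 35)
      cy <- stats::runif(1, 25, 35)
      v <- cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
      mask <- polygon_mask(v, c(60, 60))
      xc <- rep(seq_len(60) - 0.5, each = 60)
      yc <- rep(seq_len(60) - 0.5, times = 60)
      oracle <- matrix(pracma::inpolygon(xc, yc, v[, 1], v[, 2]), nrow = 60)
      expect_identical(mask, oracle)
    }
  })
})

test_that("degenerate polygons are rejected", {
  bowtie <- cbind(x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))
  expect_error(polygon_mask(bowtie, c(20, 20)), "self-intersecting")
  expect_error(polygon_mask(cbind(x = c(0, 5), y = c(0, 5)), c(20, 20)),
               "3 vertices")
  outside <- square_roi(15, 15, 10)
  expect_error(polygon_mask(outside, c(20, 20)), "outside the image")
})

test_that("ROI signal fraction counts thresholded pixels over ROI area", {
  img <- matrix(0, 100, 100)
  img[1:10, 1:30] <- 200  # 300 bright pixels inside a 50x50 corner ROI
  q <- quantify_roi_fraction(img, list(x = 0, y = 0, w = 50, h = 50), 128)
  expect_identical(q$roi_area_px, 2500L)
  expect_identical(q$signal_px, 300L)
  expect_equal(q$value, 0.12)

  # same region as a polygon ROI
  qp <- quantify_roi_fraction(img, square_roi(0, 0, 50), 128)
  expect_equal(qp$value, 0.12)

  expect_equal(quantify_roi_fraction(matrix(10, 20, 20),
                                     list(x = 0, y = 0, w = 20, h = 20),
                                     128)$value, 0)
  expect_equal(quantify_roi_fraction(matrix(200, 20, 20),
                                     list(x = 0, y = 0, w = 20, h = 20),
                                     128)$value, 1)
})

test_that("ROI fraction ignores pixels outside the ROI and scales with threshold", {
  fx <- gen_fish_image(402, c(80, 80), roi = square_roi(10, 10, 40),
                       n_signal_px = 123)
  q0 <- quantify_roi_fraction(fx$image, fx$roi, fx$threshold)
  expect_equal(q0$value, fx$truth$value)

  # permute everything outside the ROI
  mask <- polygon_mask(fx$roi, dim(fx$image))
  img2 <- fx$image
  withr::with_seed(403, {
    img2[!mask] <- sample(img2[!mask])
  })
  q1 <- quantify_roi_fraction(img2, fx$roi, fx$threshold)
  expect_identical(q1$signal_px, q0$signal_px)

  # doubling all intensities and the threshold changes nothing
  q2 <- quantify_roi_fraction(2 * fx$image, fx$roi, 2 * fx$threshold)
  expect_equal(q2$value, q0$value)
})

test_that("strip mean gray value is the arithmetic mean at fixed size", {
  img <- matrix(40, 50, 100)
  q <- quantify_strip_intensity(img, list(x = 10, y = 10, w = 20, h = 10))
  expect_equal(q$value, 40)
  # doubling intensities doubles the strip mean
  expect_equal(quantify_strip_intensity(2 * img,
                                        list(x = 10, y = 10, w = 20,
                                             h = 10))$value, 80)

  img[, 1:50] <- 0
  img[, 51:100] <- 100
  q <- quantify_strip_intensity(img, list(x = 25, y = 0, w = 50, h = 50))
  expect_equal(q$value, 50)

  expect_error(
    quantify_strip_intensity(img, list(x = 0, y = 0, w = 10, h = 10),
                             fixed_size = c(20, 10)),
    "fixed size")
  expect_error(quantify_strip_intensity(img, list(x = 90, y = 0, w = 20,
                                                  h = 10)),
               "outside the image")
})

test_that("noisy planted strip means are recovered within standard error", {
  strips <- list(list(x = 10, y = 10, w = 30, h = 20),
                 list(x = 60, y = 10, w = 30, h = 20))
  fx <- gen_strip_image(404, c(50, 100), strips, means = c(80, 30),
                        noise_sd = 5)
  for (i in 1:2) {
    q <- quantify_strip_intensity(fx$image, strips[[i]],
                                  fixed_size = c(30, 20))
    se <- 5 / sqrt(30 * 20)
    expect_lt(abs(q$value - fx$truth[i]), 4 * se)
  }
})

test_that("group comparison reports means, sems and a Student's t-test", {
  a <- c(1, 2, 3, 4)
  r <- compare_groups(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_false(r$degenerate)
  expect_equal(r$sem_a, stats::sd(a) / 2)

  # agreement with stats::t.test on arbitrary data
  b <- c(2.5, 3.5, 5, 7)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  r <- compare_groups(a, b)
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)

  # constant groups with different means: degenerate, flagged
  r <- compare_groups(c(5, 5, 5), c(7, 7, 7))
  expect_true(r$degenerate)
  expect_identical(r$t, -Inf)
  expect_identical(r$p, 0)
  expect_equal(compare_groups(c(5, 5), c(5, 5))$p, 1)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("t-test power on planted group differences matches the closed form", {
  n <- 10
  d <- 1
  reps <- 1000
  withr::with_seed(405, {
    rejected <- vapply(seq_len(reps), function(i) {
      compare_groups(stats::rnorm(n, 0, 1), stats::rnorm(n, d, 1))$p < 0.05
    }, logical(1))
  })
  expected <- stats::power.t.test(n = n, delta = d, sd = 1,
                                  sig.level = 0.05)$power
  mc_se <- sqrt(expected * (1 - expected) / reps)
  expect_lt(abs(mean(rejected) - expected), 4 * mc_se)
})

test_that("PLA signals are classified by their centroid pixel", {
  mask <- matrix(FALSE, 10, 10)
  mask[1:5, 1:5] <- TRUE
  pts <- data.frame(x = c(2.5, 8.5), y = c(2.5, 8.5))
  r <- classify_pla_signals(pts, mask)
  expect_identical(r$n_total, 2L)
  expect_identical(r$n_nuclear, 1L)
  expect_equal(r$pct_cytoplasmic, 50)

  all_in <- data.frame(x = c(1.5, 2.5), y = c(1.5, 2.5))
  expect_equal(classify_pla_signals(all_in, mask)$pct_cytoplasmic, 0)

  expect_error(classify_pla_signals(pts[0, ], mask), "undefined")
  expect_error(classify_pla_signals(data.frame(x = 99, y = 1), mask),
               "outside image")
})

test_that("grayscale images round-trip through PNG and TIFF", {
  skip_if_not_installed("png")
  skip_if_not_installed("tiff")
  img <- matrix(seq(0, 1, length.out = 400), 20, 20)
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, p)
  back <- read_gray_image(p)
  expect_equal(back, img, tolerance = 1 / 255)

  p2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(img, p2, bits.per.sample = 16L)
  expect_equal(read_gray_image(p2), img, tolerance = 1 / 65535)
})
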