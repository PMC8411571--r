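test_that("every generator is a pure function of its seed and spec", {
  planted <- data.frame(chrom = "c1", pos = c(50L, 300L), motif = "AP1",
                        strand = "+")
  g1 <- gen_genome(7, c(c1 = 1000), planted = planted)
  g2 <- gen_genome(7, c(c1 = 1000), planted = planted)
  expect_identical(g1, g2)
  g3 <- gen_genome(8, c(c1 = 1000), planted = planted)
  expect_false(identical(unclass(g1$genome), unclass(g3$genome)))

  r1 <- gen_region_set(list(c(4, 0), c(2, 1)), seed = 9)
  r2 <- gen_region_set(list(c(4, 0), c(2, 1)), seed = 9)
  expect_identical(r1, r2)

  p1 <- gen_pla_image(3, n_nuclear = 10, n_cytoplasmic = 20)
  p2 <- gen_pla_image(3, n_nuclear = 10, n_cytoplasmic = 20)
  expect_identical(p1, p2)

  i1 <- gen_fish_image(4, c(50, 50), roi = list(x = 5, y = 5, w = 20,
                                                h = 20), n_signal_px = 17)
  i2 <- gen_fish_image(4, c(50, 50), roi = list(x = 5, y = 5, w = 20,
                                                h = 20), n_signal_px = 17)
  expect_identical(i1, i2)
})

test_that("invalid planting specs are rejected", {
  expect_error(
    gen_genome(1, c(c1 = 100),
               planted = data.frame(chrom = "c1", pos = c(10L, 12L),
                                    motif = "AP1", strand = "+")),
    "overlap")
  expect_error(
    gen_genome(1, c(c1 = 100),
               planted = data.frame(chrom = "c1", pos = 98L,
                                    motif = "AP1", strand = "+")),
    "does not fit")
  expect_error(
    gen_genome(1, c(c1 = 100),
               planted = data.frame(chrom = "c1", pos = 10L,
                                    motif = "Mystery", strand = "+")),
    "not in dictionary")
  expect_error(
    gen_genome(1, c(c1 = 100),
               planted = data.frame(chrom = "cX", pos = 10L,
                                    motif = "AP1", strand = "+")),
    "unknown chromosome")
})

test_that("clean background leaves exactly the planted occurrences", {
  fx <- gen_genome(11, c(c1 = 8000, c2 = 4000),
                   planted = data.frame(
                     chrom = c("c1", "c1", "c2"),
                     pos = c(100L, 5000L, 700L),
                     motif = c("AP1", "EcRE", "AP1"), strand = "+"))
  for (chrom in c("c1", "c2")) {
    for (m in list(ap1_motif(), ecre_motif())) {
      hits <- scan_sequence(m, fx$genome[[chrom]], chrom)
      want <- fx$truth[fx$truth$chrom == chrom &
                         fx$truth$motif == m$name, ]
      expect_identical(hits$start, want$start)
    }
  }
})

test_that("without cleaning, spurious background sites can remain", {
  # at 10 kb the expected spurious AP-1 count is ~2.4, so over several
  # seeds at least one spurious site must appear
  any_spurious <- FALSE
  for (seed in 1:5) {
    fx <- gen_genome(seed, c(c1 = 10000), clean_background = FALSE)
    if (nrow(scan_sequence(ap1_motif(), fx$genome[["c1"]])) > 0) {
      any_spurious <- TRUE
    }
  }
  expect_true(any_spurious)
})

test_that("region sets realise their composition prescription exactly", {
  comp <- list(c(4, 0), c(3, 0), c(5, 1), c(0, 2))
  fx <- gen_region_set(comp, seed = 12)
  scr <- suppressMessages(screen_regions(fx$regions, fx$genome))
  expect_identical(scr$ap1_count, c(4L, 3L, 5L, 0L))
  expect_identical(scr$ecre_count, c(0L, 0L, 1L, 2L))

  expect_error(gen_region_set(list(c(50, 50)), seed = 1,
                              region_length = 300L), "infeasible")
  empty <- gen_region_set(list(), seed = 1)
  expect_identical(nrow(empty$regions), 0L)
})

test_that("peak plans translate into the planned classifications", {
  fx <- gen_region_set(list(c(3, 0)), seed = 13)
  peaksets <- gen_peaks(fx$truth,
                        data.frame(site = c(1L, 1L, 2L),
                                   factor = c("EcR", "Kay", "Jun")))
  ann <- annotate_region(fx$regions[1, ], fx$genome, ap1_motif(), peaksets)
  expect_identical(ann$category, c("green", "red", "blue"))
  expect_identical(ann$overlapping_factors[1], "EcR,Kay")

  expect_identical(gen_peaks(fx$truth, NULL), list())
  expect_error(gen_peaks(fx$truth, data.frame(site = 99L, factor = "EcR")),
               "outside the truth table")
})

test_that("image generators expose exact noiseless truths", {
  fx <- gen_fish_image(14, c(100, 100), roi = list(x = 25, y = 25, w = 50,
                                                   h = 50),
                       n_signal_px = 300)
  expect_identical(fx$truth$roi_area_px, 2500L)
  q <- quantify_roi_fraction(fx$image, fx$roi, fx$threshold)
  expect_equal(q$value, 0.12)
  expect_error(gen_fish_image(14, c(10, 10),
                              roi = list(x = 0, y = 0, w = 5, h = 5),
                              n_signal_px = 26), "cannot plant")

  strips <- list(list(x = 0, y = 0, w = 10, h = 10))
  sf <- gen_strip_image(15, c(20, 20), strips, means = 77)
  expect_equal(quantify_strip_intensity(sf$image, strips[[1]])$value, 77)

  pla <- gen_pla_image(16, n_nuclear = 36, n_cytoplasmic = 95)
  r <- classify_pla_signals(pla$centroids, pla$nuclear_mask)
  expect_identical(r$n_nuclear, 36L)
  expect_identical(r$n_cytoplasmic, 95L)
  expect_error(gen_pla_image(16, c(30, 30), n_nuclear = 1e6,
                             n_cytoplasmic = 0), "not enough")
})

test_that("child seeds separate components deterministically", {
  expect_identical(ecrap1:::child_seed(1, "genome"),
                   ecrap1:::child_seed(1, "genome"))
  expect_false(ecrap1:::child_seed(1, "genome") ==
                 ecrap1:::child_seed(1, "placement"))
  expect_false(ecrap1:::child_seed(1, "genome") ==
                 ecrap1:::child_seed(2, "genome"))
})
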