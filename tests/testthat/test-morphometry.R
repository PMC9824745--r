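test_that("equivalent circular diameter follows sqrt(4A/pi)", {
  expect_equal(round(ecd(9), 1), 3.4)
  expect_equal(round(ecd(25), 1), 5.6)
  expect_equal(ecd(pi / 4), 1.0)
  expect_true(all(diff(ecd(1:100)) > 0)) # strictly increasing
  expect_error(ecd(0), "positive")
  expect_error(ecd(-3), "positive")
})

test_that("shape ratios follow their definitions and reject bad input", {
  expect_equal(fmr(10, 10), 1.0)
  expect_error(fmr(0, 5), "positive")
  expect_equal(rar(10, 10), 1.0)
  expect_equal(rar(10, 5), 0.5)
  expect_error(rar(5, 10), "major")
  expect_error(rar(10, 0), "positive")
})

test_that("Feret diameter uses the pixel-corner caliper convention", {
  # single pixel: corner-to-corner diagonal
  expect_equal(feret_diameter(0, 0, 1), sqrt(2))
  expect_equal(feret_diameter(0, 0, 2.5), 2.5 * sqrt(2))
  # 10x1 horizontal bar: footprint 10 x 1, diagonal sqrt(101)
  expect_equal(feret_diameter(0:9, rep(0, 10), 1), sqrt(10^2 + 1^2))
  # rasterized disk of diameter 40 px: corner convention can add up to
  # sqrt(2) across the diagonal
  d <- disk_pixels(31.5, 31.5, 20)
  fer <- feret_diameter(d$cols0, d$rows0, 1)
  expect_gte(fer, 40)
  expect_lte(fer, 40 + sqrt(2))
  expect_equal(fer, bf_feret(d$cols0, d$rows0, 1))
  expect_error(feret_diameter(integer(0), integer(0)), "empty")
})

test_that("rotating calipers equals the brute-force Feret oracle", {
  withr::with_seed(7, {
    for (i in 1:200) {
      m <- random_mask_pixels(400)
      expect_equal(feret_diameter(m$cols0, m$rows0, 1),
                   bf_feret(m$cols0, m$rows0, 1))
    }
  })
})

test_that("moment ellipse fit recovers analytic shapes", {
  # axis-aligned 60 x 30 ellipse
  p <- render_particle(c(128, 128), 1, c(64, 64), 60, 30)
  idx <- which(p$mask, arr.ind = TRUE)
  ell <- fit_ellipse(idx[, 2] - 1, idx[, 1] - 1, 1)
  expect_equal(ell$major_nm, 60, tolerance = 0.02)
  expect_equal(ell$minor_nm, 30, tolerance = 0.02)

  # square of side s: both axes 2s/sqrt(3), exactly (moments are exact)
  s <- 21
  g <- expand.grid(col = 0:(s - 1), row = 0:(s - 1))
  sq <- fit_ellipse(g$col, g$row, 1)
  expect_equal(sq$major_nm, 2 * s / sqrt(3))
  expect_equal(sq$minor_nm, 2 * s / sqrt(3))

  # disk: aspect ratio within 1% of 1
  d <- disk_pixels(31.5, 31.5, 18)
  dd <- fit_ellipse(d$cols0, d$rows0, 1)
  expect_equal(dd$major_nm / dd$minor_nm, 1, tolerance = 0.01)

  # single pixel: degenerate, axes = pixel size
  one <- fit_ellipse(5, 7, 0.5)
  expect_true(one$degenerate)
  expect_equal(one$major_nm, 0.5)
})

test_that("square FMR equals sqrt(6)/2 under the corner-Feret and
           moment-ellipse conventions", {
  s <- 25
  g <- expand.grid(col = 0:(s - 1), row = 0:(s - 1))
  fer <- feret_diameter(g$col, g$row, 1)
  expect_equal(fer, s * sqrt(2))
  ell <- fit_ellipse(g$col, g$row, 1)
  expect_equal(fmr(fer, ell$major_nm), sqrt(6) / 2)
})

test_that("measure_particles populates every field consistently", {
  expect_equal(nrow(measure_particles(
    label_components(matrix(FALSE, 8, 8), 8), 1)), 0)

  sc <- clean_scene(n = 10, seed = 41)
  regs <- segment_particles(
    sc$image, seg_config(smooth = FALSE, sharpen = FALSE,
                         threshold_fraction = truth_fraction(sc),
                         min_area_px = 5))
  pt <- measure_particles(regs, sc$image$nm_per_px)
  expect_equal(nrow(pt), 10)
  expect_identical(pt$id, 1:10)
  # equation consistency, bit for bit
  expect_identical(pt$ecd_nm, sqrt(4 * pt$area_nm2 / pi))
  expect_identical(pt$fmr, pt$feret_nm / pt$major_nm)
  expect_identical(pt$rar, pt$minor_nm / pt$major_nm)
  expect_identical(pt$area_nm2, pt$area_px * sc$image$nm_per_px^2)
  expect_true(all(pt$rar > 0 & pt$rar <= 1))
  # determinism
  pt2 <- measure_particles(regs, sc$image$nm_per_px)
  expect_identical(pt, pt2)
  # 10 nm ground-truth particle recovered within 5%
  tr <- match_to_truth(pt, sc$truth)
  expect_true(all(abs(pt$ecd_nm - tr$true_ecd_nm) / tr$true_ecd_nm < 0.05))
})

test_that("lengths scale linearly and ratios are scale-free", {
  sc <- clean_scene(n = 6, seed = 43)
  regs <- segment_particles(
    sc$image, seg_config(smooth = FALSE, sharpen = FALSE,
                         threshold_fraction = truth_fraction(sc),
                         min_area_px = 5))
  a <- measure_particles(regs, 0.5)
  b <- measure_particles(regs, 1.0)
  expect_equal(b$ecd_nm, 2 * a$ecd_nm)
  expect_equal(b$feret_nm, 2 * a$feret_nm)
  expect_equal(b$major_nm, 2 * a$major_nm)
  expect_equal(b$area_nm2, 4 * a$area_nm2)
  expect_equal(b$fmr, a$fmr)
  expect_equal(b$rar, a$rar)
})

test_that("RAR of a 2:1 ellipse is rotation-stable", {
  rars <- sapply(seq(0, 170, by = 10), function(deg) {
    p <- render_particle(c(160, 160), 1, c(80, 80), 80, 40,
                         orientation = deg * pi / 180)
    idx <- which(p$mask, arr.ind = TRUE)
    ell <- fit_ellipse(idx[, 2] - 1, idx[, 1] - 1, 1)
    rar(ell$major_nm, ell$minor_nm)
  })
  expect_lte(max(rars) - min(rars), 0.03)
  expect_equal(mean(rars), 0.5, tolerance = 0.02)
})

test_that("FMR is at least 1 (within discretization) for convex shapes", {
  withr::with_seed(11, {
    for (i in 1:25) {
      maj <- runif(1, 15, 60)
      r <- runif(1, 0.3, 1)
      p <- render_particle(c(128, 128), 1, c(64, 64), maj,
                           maj * r, orientation = runif(1, 0, pi))
      idx <- which(p$mask, arr.ind = TRUE)
      ell <- fit_ellipse(idx[, 2] - 1, idx[, 1] - 1, 1)
      fer <- feret_diameter(idx[, 2] - 1, idx[, 1] - 1, 1)
      expect_gte(fmr(fer, ell$major_nm), 1 - 0.02)
    }
  })
})

test_that("particle CSV uses the fixed column order", {
  sc <- clean_scene(n = 3, seed = 47, size_px = c(192, 192))
  regs <- segment_particles(
    sc$image, seg_config(threshold_fraction = truth_fraction(sc)))
  pt <- measure_particles(regs, 0.5, source_id = "fix")
  path <- withr::local_tempfile(fileext = ".csv")
  write_particles(pt, path)
  expect_identical(
    names(read.csv(path)),
    c("id", "source_id", "area_px", "area_nm2", "ecd_nm", "feret_nm",
      "major_nm", "minor_nm", "fmr", "rar", "cx_nm", "cy_nm",
      "touches_edge"))
})
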