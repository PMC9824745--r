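test_that("preprocess filters behave on canonical inputs", {
  flat <- image_grid(matrix(120, 32, 32), 1)
  expect_identical(preprocess(flat, seg_config())$pixels, flat$pixels)

  # single bright pixel after the mean filter: 3x3 plateau of value/9
  px <- matrix(0, 15, 15); px[8, 8] <- 90
  img <- image_grid(px, 1)
  sm <- preprocess(img, seg_config(smooth = TRUE, sharpen = FALSE))
  expect_true(all(sm$pixels[7:9, 7:9] == 10))
  expect_equal(sum(sm$pixels), 90)

  # both filters off: identity
  noisy <- image_grid(matrix(sample(0:255, 400, TRUE), 20, 20), 1)
  off <- seg_config(smooth = FALSE, sharpen = FALSE)
  expect_identical(preprocess(noisy, off)$pixels, noisy$pixels)

  # dimensions always preserved, output in range
  sh <- preprocess(noisy, seg_config())
  expect_identical(dim(sh$pixels), dim(noisy$pixels))
  expect_true(all(sh$pixels >= 0 & sh$pixels <= 255))
})

test_that("percentile threshold selects exactly the dark mode", {
  px <- matrix(200, 10, 10)
  px[1, 1:5] <- 0
  img <- image_grid(px, 1)
  mask <- apply_threshold(img, 0.05)
  expect_equal(sum(mask), 5)
  expect_true(all(mask[1, 1:5]))
  # a fraction no gray level can satisfy: empty mask with a warning
  expect_warning(m2 <- apply_threshold(img, 0.01), "empty mask")
  expect_equal(sum(m2), 0)
  expect_error(apply_threshold(img, 1.2), "threshold_fraction")
})

test_that("raising the threshold fraction never shrinks the mask", {
  sc <- clean_scene(n = 8, seed = 21)
  img <- sc$image
  prev <- matrix(FALSE, nrow(img$pixels), ncol(img$pixels))
  for (f in c(0.002, 0.01, 0.02, 0.05, 0.2, 0.6)) {
    cur <- apply_threshold(img, f)
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("threshold at the true fraction recovers the particle pixels", {
  sc <- clean_scene(n = 12, seed = 13)
  truth_mask <- attr(sc$image, "truth_mask")
  mask <- apply_threshold(sc$image, truth_fraction(sc))
  expect_gte(sum(mask & truth_mask) / sum(truth_mask), 0.95)
})

test_that("component labeling honours the configured connectivity", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal touch
  m[6, 6] <- TRUE                     # far single pixel
  expect_equal(label_components(m, 8)$n, 2)
  expect_equal(label_components(m, 4)$n, 3)
  expect_equal(label_components(matrix(FALSE, 5, 5), 8)$n, 0)
  # two disjoint disks
  sc <- clean_scene(n = 2, seed = 17)
  expect_equal(label_components(attr(sc$image, "truth_mask"), 8)$n, 2)
})

test_that("labeling agrees with an independent 4-connectivity oracle", {
  skip_if_not_installed("EBImage")
  withr::with_seed(42, {
    for (i in 1:20) {
      m <- matrix(runif(900) < 0.35, 30, 30)
      ours <- label_components(m, 4)$label_map
      ref <- EBImage::bwlabel(matrix(as.numeric(m), 30, 30))
      expect_equal(max(ours), max(ref))
      # same partition: every reference component is one of ours
      for (l in seq_len(max(ref)))
        expect_equal(length(unique(ours[ref == l])), 1L)
    }
  })
})

test_that("size filtering uses inclusive bounds and renumbers labels", {
  # horizontal bars of 4, 5, 500 and 501 px in separate rows
  m <- matrix(FALSE, 9, 600)
  m[2, 1:4 + 10] <- TRUE
  m[4, 1:5 + 10] <- TRUE
  m[6, 1:500 + 10] <- TRUE
  m[8, 1:501 + 10] <- TRUE
  regs <- label_components(m, 8)
  out <- filter_by_size(regs, 5, 500)
  expect_equal(out$n, 2)
  expect_setequal(unique(out$label_map[out$label_map > 0]), 1:2)
  sizes <- tabulate(out$label_map[out$label_map > 0])
  expect_setequal(sizes, c(5, 500))
  # no upper cut
  expect_equal(filter_by_size(regs, 10, Inf)$n, 2)
  # identity range
  expect_equal(filter_by_size(regs, 1, Inf)$n, 4)
})

test_that("filters are idempotent and conserve counts", {
  sc <- clean_scene(n = 10, seed = 31)
  regs <- label_components(apply_threshold(sc$image, truth_fraction(sc)), 8)
  f1 <- filter_by_size(regs, 20, 2000)
  f2 <- filter_by_size(f1, 20, 2000)
  expect_identical(f1$label_map, f2$label_map)
  e1 <- exclude_edge_particles(f1)
  e2 <- exclude_edge_particles(e1)
  expect_identical(e1$label_map, e2$label_map)
  # removed + kept = before, at every stage
  logs <- e1$log
  for (i in seq_along(logs)[-1])
    expect_equal(logs[[i]]$kept + logs[[i]]$removed, logs[[i - 1]]$kept)
})

test_that("edge exclusion removes exactly the border-touching particles", {
  m <- matrix(FALSE, 32, 32)
  m[1:4, 10:13] <- TRUE        # touches top border
  m[15:18, 15:18] <- TRUE      # interior
  regs <- label_components(m, 8)
  out <- exclude_edge_particles(regs)
  expect_equal(out$n, 1)
  expect_true(all(which(out$label_map == 1, arr.ind = TRUE) >= 15))

  # generator's edge flags match what the filter removes
  sc <- generate_scene(scene_spec(
    n_particles = 20, image_size_px = c(256, 256), nm_per_px = 1,
    allow_edge_overlap = TRUE, noise_sd = 0,
    background = list(mean = 200, gradient = 0, texture = 0),
    scale_bar = list(length_nm = 10, on = FALSE), seed = 19))
  k <- sum(sc$truth$touches_edge)
  regs2 <- label_components(
    apply_threshold(sc$image, truth_fraction(sc)), 8)
  out2 <- exclude_edge_particles(regs2)
  expect_equal(regs2$n - out2$n, k)
})

test_that("noise-free disjoint particles are recovered at the true count
           across a band of thresholds", {
  sc <- clean_scene(n = 15, seed = 23)
  f <- truth_fraction(sc)
  for (mult in c(0.8, 0.9, 1.0, 1.1, 1.2)) {
    regs <- segment_particles(
      sc$image,
      seg_config(smooth = FALSE, sharpen = FALSE,
                 threshold_fraction = f * mult, min_area_px = 20))
    expect_equal(regs$n, 15)
  }
})
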