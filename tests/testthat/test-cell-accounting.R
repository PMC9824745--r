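test_that("cell volume converts section area times slice thickness", {
  expect_equal(round(cell_volume(20.17, 60), 2), 1.21)
  expect_equal(cell_volume(1, 1000), 1)
  expect_error(cell_volume(1, 0), "positive")
  expect_error(cell_volume(-2), "positive")
  # round trip back to the area
  expect_equal(cell_volume(7.3, 60) * 1000 / 60, 7.3)
})

test_that("volume-normalized counts reproduce the published bookkeeping", {
  expect_equal(round(normalized_count(773, 1.21)), 639)
  expect_equal(round(normalized_count(1059, 0.95)), 1115)
  expect_equal(round(normalized_count(1220, 1.81)), 674)
  expect_equal(normalized_count(0, 1), 0)
  expect_error(normalized_count(5, 0), "positive")
  # homogeneity in N and V
  expect_equal(normalized_count(3 * 50, 2), 3 * normalized_count(50, 2))
  expect_equal(normalized_count(50, 2 * 1.3),
               normalized_count(50, 1.3) / 2)
})

test_that("percent change is signed and referenced to the first count", {
  expect_equal(round(percent_change(946, 674)), -29)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 150), 50)
  expect_error(percent_change(0, 10), "positive")
})

test_that("coverage fraction is a bounded percentage", {
  expect_equal(round(coverage_fraction(63, 416), 1), 15.1)
  expect_equal(round(coverage_fraction(149, 1220), 1), 12.2)
  expect_equal(coverage_fraction(0, 100), 0)
  expect_equal(coverage_fraction(100, 100), 100)
  expect_error(coverage_fraction(10, 5), "n_total")
  expect_error(coverage_fraction(5, 0), "positive")
  withr::with_seed(8, {
    n_tot <- sample(1:1000, 50, TRUE)
    n_hr <- floor(runif(50) * (n_tot + 1))
    cv <- coverage_fraction(n_hr, n_tot)
    expect_true(all(cv >= 0 & cv <= 100))
  })
})

test_that("cell_summary assembles the accounting table", {
  cs <- cell_summary(c("au24", "au51"), c(20.17, 15.83), c(773, 1059))
  expect_equal(cs$cell_volume_um3, c(1.2102, 0.9498))
  expect_equal(round(cs$normalized_count), c(639, 1115))
})

test_that("a whole-image ROI reproduces the global analysis", {
  sc <- clean_scene(n = 10, seed = 51, size_px = c(400, 400))
  img <- sc$image
  cfg <- seg_config(smooth = FALSE, sharpen = FALSE,
                    threshold_fraction = truth_fraction(sc),
                    min_area_px = 5)
  side_nm <- 400 * img$nm_per_px
  lp <- local_psd(img, list(roi_spec(c(0, 0), side_nm, "full")), cfg)
  global <- measure_particles(segment_particles(img, cfg), img$nm_per_px)
  expect_equal(lp$table$n, nrow(global))
  expect_equal(sort(lp$particles$full$area_px), sort(global$area_px))
})

test_that("ROI handling: empty ROIs are fine, outside ROIs are not", {
  img <- image_grid(matrix(200, 200, 200), 1)
  img$pixels[50:60, 50:60] <- 50 # one dark block
  cfg <- seg_config(smooth = FALSE, sharpen = FALSE,
                    threshold_fraction = 0.01, min_area_px = 5)
  lp <- local_psd(img, list(roi_spec(c(100, 100), 80, "empty")), cfg)
  expect_equal(lp$table$n, 0)
  expect_null(lp$summaries$empty)
  expect_error(
    local_psd(img, list(roi_spec(c(150, 150), 80, "oob")), cfg),
    "oob")
})

test_that("disjoint ROI tiles recover the global particles minus
           tile-border contacts", {
  sc <- clean_scene(n = 12, seed = 57, size_px = c(480, 480))
  img <- sc$image
  f <- truth_fraction(sc)
  cfg <- seg_config(smooth = FALSE, sharpen = FALSE,
                    threshold_fraction = f, min_area_px = 5)
  side_nm <- 240 * img$nm_per_px
  tiles <- list(
    roi_spec(c(0, 0), side_nm, "tl"), roi_spec(c(side_nm, 0), side_nm, "tr"),
    roi_spec(c(0, side_nm), side_nm, "bl"),
    roi_spec(c(side_nm, side_nm), side_nm, "br"))
  lp <- local_psd(img, tiles, cfg)
  tiled <- purrr::list_rbind(unname(lp$particles))
  global <- measure_particles(segment_particles(img, cfg), img$nm_per_px)
  # every tiled particle matches a global particle; the difference is
  # exactly the particles cut by tile borders
  expect_lte(nrow(tiled), nrow(global))
  for (i in seq_len(nrow(tiled))) {
    d <- sqrt((global$cx_nm - tiled$cx_nm[i])^2 +
              (global$cy_nm - tiled$cy_nm[i])^2)
    expect_lt(min(d), 2)
  }
  # particles lost to tiling must straddle an interior tile boundary
  lost <- nrow(global) - nrow(tiled)
  straddle <- sum(
    abs(global$cx_nm - side_nm) < global$feret_nm |
    abs(global$cy_nm - side_nm) < global$feret_nm)
  expect_lte(lost, straddle)
})

test_that("ROI comparison reports deviations and flags extremes only", {
  rep1 <- compare_rois(tibble::tibble(label = LETTERS[1:5],
                                      n = c(68, 65, 71, 64, 90)))
  expect_equal(rep1$others_mean[5], 67)
  expect_equal(rep1$deviation[5], 23)
  expect_true(rep1$flagged[5])
  expect_false(any(rep1$flagged[1:4]))

  same <- compare_rois(tibble::tibble(label = LETTERS[1:4], n = rep(70, 4)))
  expect_false(any(same$flagged))

  expect_error(compare_rois(tibble::tibble(label = "A", n = 5)),
               "at least two")
})

test_that("a planted high-density ROI is flagged", {
  # one scene region seeded with 10x the particle density
  sc <- clean_scene(n = 30, seed = 61, size_px = c(600, 600))
  img <- sc$image
  # plant extra dark blocks densely in the top-left 150 px tile
  withr::with_seed(62, {
    for (i in 1:25) {
      r <- sample(10:130, 1); c <- sample(10:130, 1)
      img$pixels[r:(r + 5), c:(c + 5)] <- 55
    }
  })
  side_px <- 150
  side_nm <- side_px * img$nm_per_px
  origins <- list(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(0, 1), c(1, 1))
  tiles <- purrr::imap(origins, function(o, i)
    roi_spec(c(o[1], o[2]) * side_nm, side_nm, paste0("T", i)))
  # per-ROI thresholds, as a practitioner would set them from each
  # window's own dark-pixel content
  cfgs <- purrr::map(origins, function(o) {
    rows <- o[2] * side_px + seq_len(side_px)
    cols <- o[1] * side_px + seq_len(side_px)
    f <- max(mean(img$pixels[rows, cols] < 150), 1e-4)
    seg_config(smooth = FALSE, sharpen = FALSE,
               threshold_fraction = f, min_area_px = 5)
  })
  rep_ <- compare_rois(local_psd(img, tiles, cfgs)$table)
  expect_true(rep_$flagged[1])
  expect_false(any(rep_$flagged[-1]))
})
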