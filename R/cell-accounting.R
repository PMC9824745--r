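#' Sampled cell volume from a section area
#'
#' A microtome ultrathin section samples a slab of the cell; the sampled
#' volume is the measured cell cross-section area times the section
#' thickness: `V [um^3] = area [um^2] * thickness [nm] / 1000`.
#'
#' @param cell_area_um2 Cell cross-section area in um^2 (> 0).
#' @param slice_thickness_nm Section thickness in nm (default 60).
#' @return Volume in um^3.
#' @examples
#' cell_volume(20.17) # ~1.21 um^3
#' @export
cell_volume <- function(cell_area_um2, slice_thickness_nm = 60) {
  if (any(cell_area_um2 <= 0) || any(slice_thickness_nm <= 0))
    abort("area and thickness must be positive")
  cell_area_um2 * slice_thickness_nm / 1000
}

#' Volume-normalized particle count
#'
#' Particle count per standard 1.00 um^3 of cell: `N / V`.
#'
#' @param n_particles Detected particle count (>= 0).
#' @param cell_volume_um3 Sampled cell volume in um^3 (> 0).
#' @return Particles per um^3.
#' @examples
#' normalized_count(773, 1.21) # ~639
#' @export
normalized_count <- function(n_particles, cell_volume_um3) {
  if (any(cell_volume_um3 <= 0)) abort("`cell_volume_um3` must be positive")
  if (any(n_particles < 0)) abort("`n_particles` must be >= 0")
  n_particles / cell_volume_um3
}

#' Signed percent change between two counts
#'
#' `100 * (new - ref) / ref`; negative for a decrease.
#'
#' @param count_ref Reference count (> 0).
#' @param count_new New count.
#' @return Signed percentage.
#' @examples
#' percent_change(946, 674) # ~ -29
#' @export
percent_change <- function(count_ref, count_new) {
  if (any(count_ref <= 0)) abort("`count_ref` must be positive")
  100 * (count_new - count_ref) / count_ref
}

#' Coverage fraction of a high-resolution subset
#'
#' Percentage of all particles in a cell that a set of high-resolution
#' fields captured: `100 * n_hr / n_total`.
#'
#' @param n_hr Particles detected in the high-resolution fields
#'   (`0 <= n_hr <= n_total`).
#' @param n_total All particles in the cell (> 0).
#' @return Percentage in `[0, 100]`.
#' @examples
#' coverage_fraction(63, 416) # ~15.1
#' @export
coverage_fraction <- function(n_hr, n_total) {
  if (any(n_total <= 0)) abort("`n_total` must be positive")
  if (any(n_hr < 0) || any(n_hr > n_total))
    abort("`n_hr` must lie in [0, n_total]")
  100 * n_hr / n_total
}

#' Per-cell particle accounting
#'
#' Bundles the cell's section area, the sampled volume, and raw and
#' volume-normalized particle counts into one tidy row per cell.
#'
#' @param cell_id Identifier(s).
#' @param cell_area_um2 Cell cross-section area(s) in um^2.
#' @param n_particles Detected particle count(s).
#' @param slice_thickness_nm Section thickness in nm (default 60).
#' @return Tibble with columns `cell_id`, `cell_area_um2`,
#'   `slice_thickness_nm`, `cell_volume_um3`, `n_particles`,
#'   `normalized_count`.
#' @export
cell_summary <- function(cell_id, cell_area_um2, n_particles,
                         slice_thickness_nm = 60) {
  v <- cell_volume(cell_area_um2, slice_thickness_nm)
  tibble(cell_id = as.character(cell_id),
         cell_area_um2 = cell_area_um2,
         slice_thickness_nm = slice_thickness_nm,
         cell_volume_um3 = v,
         n_particles = n_particles,
         normalized_count = normalized_count(n_particles, v))
}

#' Square region of interest
#'
#' @param origin_nm `c(x, y)` of the ROI's top-left corner in nm.
#' @param side_nm Side length in nm (default 500, a 500 x 500 nm^2 window).
#' @param label Short identifier (e.g. "A").
#' @return An `roi_spec` list.
#' @export
roi_spec <- function(origin_nm, side_nm = 500, label = "ROI") {
  if (length(origin_nm) != 2 || any(origin_nm < 0))
    abort("`origin_nm` must be two non-negative numbers")
  if (side_nm <= 0) abort("`side_nm` must be positive")
  structure(list(origin_nm = as.numeric(origin_nm),
                 side_nm = as.numeric(side_nm),
                 label = as.character(label)),
            class = "roi_spec")
}

#' Local particle-size distributions in regions of interest
#'
#' Crops each square ROI out of the image and runs the full detection and
#' morphometry workflow on it independently — including edge exclusion at
#' the ROI borders, exactly as at image borders — then summarizes each
#' ROI's particle areas. Each ROI may carry its own threshold via a list of
#' configs (local brightness varies slightly across a cell).
#'
#' @param image An [image_grid()].
#' @param rois List of [roi_spec()] objects (>= 1).
#' @param config A single [seg_config()], or a list of configs, one per ROI.
#' @param bin_width_nm2 Histogram bin width for the per-ROI area PSD
#'   (default 50 nm^2, so the smallest size class is 0-50 nm^2).
#' @return `list(table = <tibble>, summaries = <named list of psd_summary>,
#'   particles = <named list of tibbles>)`. The table has one row per ROI:
#'   `label`, `n`, `mean_area_nm2`, `se_area_nm2`, `smallest_class_fraction`
#'   (fraction of particles in the first size class),
#'   `threshold_fraction`. ROIs with no particles get `n = 0` rows and a
#'   `NULL` summary, not an error.
#' @export
local_psd <- function(image, rois, config = seg_config(),
                      bin_width_nm2 = 50) {
  assert_image_grid(image)
  if (length(rois) < 1) abort("need at least one ROI")
  configs <- if (inherits(config, "seg_config"))
    rep(list(config), length(rois)) else config
  if (length(configs) != length(rois))
    abort("`config` must be one seg_config or one per ROI")
  npx <- image$nm_per_px
  w <- ncol(image$pixels); h <- nrow(image$pixels)
  summaries <- list(); particles <- list(); rows <- list()
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    x0 <- round(roi$origin_nm[1] / npx)
    y0 <- round(roi$origin_nm[2] / npx)
    side <- round(roi$side_nm / npx)
    if (x0 < 0 || y0 < 0 || x0 + side > w || y0 + side > h)
      abort(sprintf("ROI '%s' does not lie fully inside the image",
                    roi$label))
    sub <- crop(image, x0, y0, side, side)
    sub$source_id <- paste0(image$source_id, ":", roi$label)
    regs <- segment_particles(sub, configs[[i]])
    pt <- measure_particles(regs, npx, source_id = sub$source_id)
    # map centroids back to whole-image coordinates
    if (nrow(pt) > 0) {
      pt$cx_nm <- pt$cx_nm + x0 * npx
      pt$cy_nm <- pt$cy_nm + y0 * npx
    }
    particles[[roi$label]] <- pt
    if (nrow(pt) > 0) {
      s <- psd_histogram(pt$area_nm2, bin_width_nm2,
                         metric_name = paste0("area_nm2:", roi$label))
      summaries[[roi$label]] <- s
      st <- summary_stats(pt$area_nm2)
      smallest <- mean(pt$area_nm2 < bin_width_nm2)
      rows[[i]] <- tibble(label = roi$label, n = nrow(pt),
                          mean_area_nm2 = st$mean, se_area_nm2 = st$se,
                          smallest_class_fraction = smallest,
                          threshold_fraction =
                            configs[[i]]$threshold_fraction)
    } else {
      summaries[roi$label] <- list(NULL)
      rows[[i]] <- tibble(label = roi$label, n = 0L,
                          mean_area_nm2 = NA_real_, se_area_nm2 = NA_real_,
                          smallest_class_fraction = NA_real_,
                          threshold_fraction =
                            configs[[i]]$threshold_fraction)
    }
  }
  list(table = list_rbind(rows), summaries = summaries,
       particles = particles)
}

#' Compare regions of interest for local hotspots
#'
#' Tabulates per-ROI particle count, mean size and smallest-class fraction,
#' with each ROI's deviation from the mean of the *other* ROIs. A ROI is
#' flagged as a candidate hotspot only when its count deviates from the
#' others' mean by more than twice their standard deviation (leave-one-out;
#' with a handful of ROIs an extreme region would otherwise inflate the
#' pooled spread enough to hide itself).
#'
#' @param roi_table The `table` element of [local_psd()], or any tibble with
#'   columns `label` and `n` (optionally `mean_area_nm2`,
#'   `smallest_class_fraction`).
#' @return The input with added columns `others_mean`, `deviation`
#'   (count minus others' mean) and `flagged`.
#' @examples
#' compare_rois(tibble::tibble(label = LETTERS[1:5],
#'                             n = c(68, 65, 71, 64, 90)))
#' @export
compare_rois <- function(roi_table) {
  if (nrow(roi_table) < 2) abort("need at least two ROI summaries")
  n <- roi_table$n
  k <- length(n)
  others_mean <- (sum(n) - n) / (k - 1)
  others_sd <- map_dbl(seq_len(k), function(i) sd(n[-i]))
  dev <- n - others_mean
  flagged <- if (k > 2) abs(dev) > 2 * others_sd & others_sd >= 0 &
    abs(dev) > 0 else rep(FALSE, k)
  roi_table |>
    mutate(others_mean = others_mean, deviation = dev,
           flagged = as.logical(flagged))
}

#' Write a hotspot report
#'
#' @param report Output of [compare_rois()].
#' @param path CSV path; a JSON twin is written alongside.
#' @return Invisibly, `path`.
#' @export
write_roi_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(report, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
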