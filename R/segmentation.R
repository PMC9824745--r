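#' Segmentation settings
#'
#' Parameters of the particle-detection workflow: optional smoothing and
#' sharpening, a percentile threshold, an inclusive pixel size range, and
#' edge exclusion. Mirrors the per-image settings a practitioner would use
#' in ImageJ's Analyze Particles workflow.
#'
#' `threshold_fraction` is the fraction of image pixels assigned to
#' foreground: the darkest pixels are selected by choosing the largest gray
#' cutoff whose cumulative histogram fraction does not exceed it. Published
#' per-image thresholds quoted in percent (e.g. 0.2) correspond to
#' `threshold_fraction = 0.002`.
#'
#' @param smooth,sharpen Enable the 3x3 mean filter / 3x3 sharpen filter.
#' @param threshold_fraction Foreground fraction in (0, 1).
#' @param min_area_px,max_area_px Inclusive pixel-count bounds for surviving
#'   regions; `max_area_px = Inf` disables the upper cut.
#' @param exclude_edges Remove regions touching the image border (default on).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @return A `seg_config` list.
#' @export
seg_config <- function(smooth = TRUE, sharpen = TRUE,
                       threshold_fraction = 0.002,
                       min_area_px = 5L, max_area_px = Inf,
                       exclude_edges = TRUE, connectivity = 8L) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    abort("`threshold_fraction` must lie in (0, 1)")
  if (min_area_px < 1) abort("`min_area_px` must be >= 1")
  if (max_area_px <= min_area_px)
    abort("`max_area_px` must exceed `min_area_px`")
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8")
  structure(
    list(smooth = isTRUE(smooth), sharpen = isTRUE(sharpen),
         threshold_fraction = threshold_fraction,
         min_area_px = as.numeric(min_area_px),
         max_area_px = as.numeric(max_area_px),
         exclude_edges = isTRUE(exclude_edges),
         connectivity = as.integer(connectivity)),
    class = "seg_config"
  )
}

# 3x3 convolution with edge replication; kernel given as 3x3 matrix
convolve3 <- function(px, kernel) {
  h <- nrow(px); w <- ncol(px)
  pad <- rbind(px[1, , drop = FALSE], px, px[h, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, w, drop = FALSE])
  out <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    k <- kernel[dr + 2, dc + 2]
    if (k != 0)
      out <- out + k * pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  out
}

#' Preprocess an image before thresholding
#'
#' Applies, in order, a 3x3 uniform mean filter (smoothing) and the classic
#' 3x3 sharpen kernel (center 12, all eight neighbours -1, normalized by 4 —
#' the kernel sums to 1, so flat fields are unchanged). Output is rounded
#' and clipped back to `[0, 255]`; dimensions are preserved. Image borders
#' are handled by edge replication.
#'
#' @param image An [image_grid()].
#' @param config A [seg_config()]; only its `smooth`/`sharpen` flags are used.
#' @return The filtered [image_grid()].
#' @export
preprocess <- function(image, config = seg_config()) {
  assert_image_grid(image)
  px <- image$pixels
  if (config$smooth)
    px <- convolve3(px, matrix(1 / 9, 3, 3))
  if (config$sharpen) {
    k <- matrix(-1, 3, 3); k[2, 2] <- 12
    px <- convolve3(px, k / 4)
  }
  image$pixels <- pmin(pmax(round(px), 0L), 255L)
  storage.mode(image$pixels) <- "integer"
  image
}

#' Percentile threshold: select the darkest fraction of pixels
#'
#' Chooses the largest gray cutoff `g` such that the cumulative histogram
#' fraction of pixels with intensity `<= g` does not exceed
#' `threshold_fraction`, and returns the mask of pixels at or below that
#' cutoff. The selected fraction is therefore as close as possible to the
#' request without overshooting at any gray-level boundary. Deterministic;
#' raising the fraction can only grow the mask.
#'
#' @param image An [image_grid()].
#' @param threshold_fraction Target foreground fraction in (0, 1).
#' @return A logical matrix mask (TRUE = foreground). If no gray level
#'   qualifies the mask is empty and a warning is issued.
#' @export
apply_threshold <- function(image, threshold_fraction) {
  assert_image_grid(image)
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    abort("`threshold_fraction` must lie in (0, 1)")
  px <- image$pixels
  counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
  cumfrac <- cumsum(counts) / length(px)
  ok <- which(cumfrac <= threshold_fraction)
  if (length(ok) == 0) {
    warn(sprintf(
      "no gray level selects <= %.4g of pixels; empty mask returned",
      threshold_fraction))
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  cutoff <- max(ok) - 1L # back to 0-based gray level
  px <= cutoff
}

#' Label connected foreground components
#'
#' Two-pass union-find connected-component labeling under 4- or
#' 8-connectivity. Labels are consecutive positive integers assigned in
#' raster order of first appearance; 0 is background.
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8 (default 8, matching ImageJ's particle
#'   analysis).
#' @param provenance Optional list recording the settings that produced the
#'   mask; carried along for the run manifest.
#' @return A `labeled_regions` object: `label_map` (integer matrix),
#'   `n` (number of regions), `connectivity`, and a `log` of filter stages.
#' @export
label_components <- function(mask, connectivity = 8L, provenance = list()) {
  if (!is.logical(mask) || !is.matrix(mask))
    abort("`mask` must be a logical matrix")
  lab <- label_components_cpp(mask, as.integer(connectivity))
  new_labeled_regions(lab, as.integer(connectivity),
                      log = list(list(stage = "label",
                                      kept = max(lab), removed = 0L)),
                      provenance = provenance)
}

new_labeled_regions <- function(label_map, connectivity, log = list(),
                                provenance = list()) {
  structure(
    list(label_map = label_map, n = max(label_map),
         connectivity = connectivity, log = log, provenance = provenance),
    class = "labeled_regions"
  )
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d regions, %d-connectivity, %d x %d px\n",
              x$n, x$connectivity, nrow(x$label_map), ncol(x$label_map)))
  for (l in x$log)
    cat(sprintf("  %-12s kept %5d removed %5d\n",
                l$stage, l$kept, l$removed))
  invisible(x)
}

# pixel counts per label
region_sizes <- function(regions) {
  tabulate(regions$label_map[regions$label_map > 0L], nbins = regions$n)
}

# renumber surviving labels consecutively, preserving order
relabel <- function(regions, keep, stage, removed_note = NULL) {
  map <- integer(regions$n)
  map[keep] <- seq_along(keep)
  lm <- regions$label_map
  pos <- lm > 0L
  lm[pos] <- map[lm[pos]]
  entry <- list(stage = stage, kept = length(keep),
                removed = regions$n - length(keep))
  if (!is.null(removed_note)) entry <- c(entry, removed_note)
  new_labeled_regions(lm, regions$connectivity,
                      log = c(regions$log, list(entry)),
                      provenance = regions$provenance)
}

#' Remove regions outside an inclusive pixel size range
#'
#' Regions with pixel count strictly below `min_area_px` or strictly above
#' `max_area_px` are dropped (bounds inclusive, so a 5 px region survives a
#' 5–500 range); survivors are renumbered consecutively. The stage log
#' records how many regions were removed as too small and as too large.
#'
#' @param regions A `labeled_regions` object.
#' @param min_area_px,max_area_px Inclusive bounds; `Inf` disables the upper
#'   cut.
#' @return Filtered `labeled_regions`.
#' @export
filter_by_size <- function(regions, min_area_px, max_area_px = Inf) {
  stopifnot(inherits(regions, "labeled_regions"))
  sz <- region_sizes(regions)
  keep <- which(sz >= min_area_px & sz <= max_area_px)
  relabel(regions, keep, "size_filter",
          removed_note = list(too_small = sum(sz < min_area_px),
                              too_large = sum(sz > max_area_px)))
}

#' Remove regions touching the image border
#'
#' Any region owning at least one pixel in the first or last row or column
#' is removed; survivors are renumbered consecutively.
#'
#' @param regions A `labeled_regions` object.
#' @return Filtered `labeled_regions`.
#' @export
exclude_edge_particles <- function(regions) {
  stopifnot(inherits(regions, "labeled_regions"))
  lm <- regions$label_map
  border <- unique(c(lm[1, ], lm[nrow(lm), ], lm[, 1], lm[, ncol(lm)]))
  border <- border[border > 0L]
  keep <- setdiff(seq_len(regions$n), border)
  relabel(regions, keep, "edge_exclude")
}

#' Run the full detection workflow on one image
#'
#' Convenience wrapper: preprocess (optional smooth + sharpen), percentile
#' threshold, connected-component labeling, inclusive size filtering, and
#' edge exclusion, as configured by a [seg_config()].
#'
#' @param image An [image_grid()].
#' @param config A [seg_config()].
#' @param verbose Emit one message per filter stage (stage, kept, removed).
#' @return A `labeled_regions` object whose `log` records every stage and
#'   whose `provenance` echoes the applied config.
#' @examples
#' sc <- generate_scene(scene_spec(n_particles = 8, noise_sd = 0, seed = 2))
#' segment_particles(sc$image, seg_config(threshold_fraction = 0.02))
#' @export
segment_particles <- function(image, config = seg_config(),
                              verbose = FALSE) {
  assert_image_grid(image)
  stopifnot(inherits(config, "seg_config"))
  pre <- preprocess(image, config)
  mask <- apply_threshold(pre, config$threshold_fraction)
  regions <- label_components(mask, config$connectivity,
                              provenance = unclass(config))
  regions <- filter_by_size(regions, config$min_area_px, config$max_area_px)
  if (config$exclude_edges)
    regions <- exclude_edge_particles(regions)
  if (verbose)
    for (l in regions$log)
      inform(sprintf("[%s] %s: kept %d, removed %d",
                     image$source_id, l$stage, l$kept, l$removed))
  regions
}
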