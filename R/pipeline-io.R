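#' Read a micrograph from disk
#'
#' Reads PNG, TIFF or JPEG, converts to 8-bit grayscale (Rec. 709 luminance
#' for color inputs) and attaches the pixel calibration.
#'
#' @param path Image file (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @param nm_per_px Physical pixel size in nm.
#' @param source_id Identifier; defaults to the file name.
#' @return An [image_grid()].
#' @export
read_image <- function(path, nm_per_px, source_id = basename(path)) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        abort("the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    abort(sprintf("unsupported image format '.%s' (%s)", ext, path))
  )
  if (length(dim(arr)) == 3) {
    # luminance; alpha (4th channel) ignored
    arr <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
  }
  if (length(arr) == 0) abort(sprintf("zero-size image: %s", path))
  image_grid(round(arr * 255), nm_per_px, source_id = source_id)
}

#' Write an image as 8-bit grayscale
#'
#' @param image An [image_grid()].
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  assert_image_grid(image)
  g <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(g, path),
    tif = ,
    tiff = tiff::writeTIFF(g, path, bits.per.sample = 8L),
    abort(sprintf("unsupported output format '.%s'", ext))
  )
  invisible(path)
}

#' Pixel calibration
#'
#' Binds the pixels-per-micrometre scale ratio to its nm-per-pixel inverse:
#' `nm_per_px = 1000 / px_per_um`.
#'
#' @param px_per_um Scale ratio in px/um (e.g. 736).
#' @param method How the ratio was obtained: `"manual"` (instrument
#'   metadata / user supplied) or `"scale_bar"`.
#' @return A `calibration` list with `px_per_um`, `nm_per_px`, `method`.
#' @export
calibration <- function(px_per_um, method = c("manual", "scale_bar")) {
  if (px_per_um <= 0) abort("`px_per_um` must be positive")
  structure(list(px_per_um = px_per_um, nm_per_px = 1000 / px_per_um,
                 method = match.arg(method)),
            class = "calibration")
}

#' Calibrate from a rendered scale bar
#'
#' Measures the longest horizontal run of saturated (intensity 255) pixels
#' in a band of rows and converts the known bar length into a px/um ratio.
#'
#' @param image An [image_grid()] (its `nm_per_px` is ignored).
#' @param bar_length_nm Physical bar length in nm.
#' @param bar_row_hint Optional center row (1-based) of the band searched
#'   (+/- 20 rows); by default the bottom quarter of the image is scanned.
#' @return A `calibration` with `method = "scale_bar"`.
#' @export
calibrate_from_bar <- function(image, bar_length_nm, bar_row_hint = NULL) {
  assert_image_grid(image)
  px <- image$pixels
  h <- nrow(px)
  rows <- if (is.null(bar_row_hint)) {
    seq(max(1L, floor(3 * h / 4)), h)
  } else {
    seq(max(1L, bar_row_hint - 20L), min(h, bar_row_hint + 20L))
  }
  longest <- 0L
  for (r in rows) {
    v <- px[r, ] == 255
    if (!any(v)) next
    runs <- rle(v)
    best <- max(runs$lengths[runs$values])
    longest <- max(longest, best)
  }
  if (longest < 10L)
    abort(paste0("no saturated run of >= 10 px found; ",
                 "supply the calibration manually"))
  calibration(longest / (bar_length_nm / 1000), method = "scale_bar")
}

#' Crop a sub-image
#'
#' Extracts a rectangle, preserving the calibration and recording the
#' offset in attribute `"crop_offset_px"` (0-based `c(x0, y0)`) so particle
#' coordinates measured on the crop can be mapped back to the original
#' frame.
#'
#' @param image An [image_grid()].
#' @param x0,y0 0-based top-left corner of the rectangle (column, row).
#' @param width,height Rectangle size in pixels.
#' @return The cropped [image_grid()].
#' @export
crop <- function(image, x0, y0, width, height) {
  assert_image_grid(image)
  w <- ncol(image$pixels); h <- nrow(image$pixels)
  if (x0 < 0 || y0 < 0 || width < 1 || height < 1 ||
      x0 + width > w || y0 + height > h)
    abort("crop rectangle does not lie inside the image")
  out <- image_grid(image$pixels[(y0 + 1):(y0 + height),
                                 (x0 + 1):(x0 + width), drop = FALSE],
                    image$nm_per_px, source_id = image$source_id)
  attr(out, "crop_offset_px") <- c(x0 = x0, y0 = y0)
  out
}

#' Read a pipeline run configuration
#'
#' YAML with one block per image mirroring the per-image settings of a TEM
#' evaluation sheet: path, scale ratio (px/um) or nm/px, threshold (percent
#' of pixels, as printed in such tables, or as a fraction), pixel size
#' range (e.g. `"5-500"` or `"10-inf"`), plus analysis mode, ROIs and
#' output directory. `zoom` is carried as inert metadata.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$images) || length(cfg$images) == 0)
    abort("config must list at least one image")
  images <- map(cfg$images, parse_image_block)
  structure(
    list(images = images,
         mode = cfg$mode %||% "whole_cell",
         rois = map(cfg$rois %||% list(), function(r)
           roi_spec(c(r$x_nm, r$y_nm), r$side_nm %||% 500,
                    r$label %||% "ROI")),
         out_dir = cfg$out_dir %||% ".",
         seed = cfg$seed %||% NULL),
    class = "run_config"
  )
}

parse_image_block <- function(b) {
  npx <- if (!is.null(b$nm_per_px)) b$nm_per_px
         else if (!is.null(b$px_per_um)) 1000 / b$px_per_um
         else abort(sprintf("image '%s': need px_per_um or nm_per_px",
                            b$path %||% "?"))
  range <- parse_px_range(b$range %||% "1-inf")
  thr <- if (!is.null(b$threshold_percent)) b$threshold_percent / 100
         else b$threshold_fraction %||% 0.002
  list(
    path = b$path,
    id = b$id %||% basename(b$path %||% "image"),
    zoom = b$zoom %||% NA, # metadata only, never enters computation
    nm_per_px = npx,
    cell_area_um2 = b$cell_area_um2 %||% NA_real_,
    config = seg_config(
      smooth = b$smooth %||% TRUE, sharpen = b$sharpen %||% TRUE,
      threshold_fraction = thr,
      min_area_px = range[1], max_area_px = range[2],
      exclude_edges = b$exclude_edges %||% TRUE,
      connectivity = b$connectivity %||% 8L
    )
  )
}

# "5-500", "10-inf" -> c(5, 500) / c(10, Inf)
parse_px_range <- function(s) {
  parts <- strsplit(as.character(s), "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort(sprintf("bad size range '%s'", s))
  lo <- as.numeric(parts[1])
  hi <- if (tolower(parts[2]) == "inf") Inf else as.numeric(parts[2])
  c(lo, hi)
}

#' Run the full analysis pipeline over a configuration
#'
#' For every configured image: read, segment, measure, and write a
#' per-image particle CSV; then pool the particles, write the pooled area
#' and ECD distribution summaries and the roundness-class table, a per-cell
#' accounting table (when cell areas are configured), or a per-ROI report
#' in local mode; and a JSON run manifest with the config hash and
#' per-stage counts. A failing image is reported and skipped; the rest of
#' the run proceeds. Deterministic for a fixed config.
#'
#' @param config A `run_config` from [read_run_config()], or a path to one.
#' @return Invisibly, a list with `particles` (pooled tibble), `per_image`
#'   (named list), `outputs` (paths written) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  per_image <- list(); outputs <- character(0); stage_counts <- list()
  roi_reports <- list()
  for (im in config$images) {
    res <- tryCatch({
      img <- read_image(im$path, im$nm_per_px, source_id = im$id)
      if (config$mode == "local" && length(config$rois) > 0) {
        lp <- local_psd(img, config$rois, im$config)
        rep_ <- compare_rois(lp$table)
        pr <- file.path(config$out_dir,
                        paste0("roi-report-", im$id, ".csv"))
        write_roi_report(rep_, pr)
        roi_reports[[im$id]] <- rep_
        outputs <- c(outputs, pr)
        pt <- list_rbind(unname(lp$particles))
        list(particles = pt, log = list())
      } else {
        regs <- segment_particles(img, im$config)
        pt <- measure_particles(regs, im$nm_per_px, source_id = im$id)
        list(particles = pt, log = regs$log)
      }
    }, error = function(e) {
      warn(sprintf("image '%s' failed at analysis: %s", im$id,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    per_image[[im$id]] <- res$particles
    stage_counts[[im$id]] <- res$log
    p <- file.path(config$out_dir, paste0("particles-", im$id, ".csv"))
    write_particles(res$particles, p)
    outputs <- c(outputs, p)
  }
  pooled <- if (length(per_image) > 0) list_rbind(unname(per_image))
            else NULL
  if (!is.null(pooled) && nrow(pooled) > 0) {
    a <- psd_histogram(pooled$area_nm2, 10, metric_name = "area_nm2")
    e <- psd_histogram(pooled$ecd_nm, 1, metric_name = "ecd_nm")
    pa <- file.path(config$out_dir, "psd-area.csv")
    pe <- file.path(config$out_dir, "psd-ecd.csv")
    write_psd(a, pa); write_psd(e, pe)
    cf <- class_fractions(pooled)
    pc <- file.path(config$out_dir, "class-fractions.csv")
    write.csv(cf, pc, row.names = FALSE)
    outputs <- c(outputs, pa, pe, pc)
  }
  areas <- map_dbl(config$images, "cell_area_um2")
  if (config$mode == "whole_cell" && any(!is.na(areas))) {
    ok <- !is.na(areas)
    cs <- cell_summary(
      map_chr(config$images[ok], "id"), areas[ok],
      map_int(config$images[ok], function(im)
        nrow(per_image[[im$id]]) %||% 0L))
    pcs <- file.path(config$out_dir, "cell-summary.csv")
    write.csv(cs, pcs, row.names = FALSE)
    outputs <- c(outputs, pcs)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("nanomorph")),
    config_hash = hash(config),
    mode = config$mode,
    images = map(config$images, function(im)
      list(id = im$id, nm_per_px = im$nm_per_px,
           threshold_fraction = im$config$threshold_fraction,
           min_area_px = im$config$min_area_px,
           max_area_px = if (is.finite(im$config$max_area_px))
             im$config$max_area_px else "inf")),
    stage_counts = stage_counts,
    n_pooled = if (is.null(pooled)) 0L else nrow(pooled)
  )
  pm <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, pm)
  invisible(list(particles = pooled, per_image = per_image,
                 roi_reports = roi_reports,
                 outputs = outputs, manifest = manifest))
}
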