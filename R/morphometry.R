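#' Equivalent circular diameter
#'
#' Diameter of the circle whose area equals the measured particle area:
#' `ECD = sqrt(4 A / pi)`. Strictly increasing in area. Vectorized.
#'
#' @param area_nm2 Particle area(s) in nm^2 (> 0).
#' @return ECD in nm.
#' @examples
#' ecd(9)  # ~3.4 nm
#' ecd(25) # ~5.6 nm
#' @export
ecd <- function(area_nm2) {
  if (any(area_nm2 <= 0)) abort("`area_nm2` must be positive")
  sqrt(4 * area_nm2 / pi)
}

#' Feret major-axis ratio
#'
#' Ratio of the maximum Feret diameter to the full major axis of the fitted
#' ellipse, `FMR = D_f / a`. 1 for an ideal ellipse; larger for angular or
#' irregular outlines.
#'
#' @param feret_nm Maximum Feret diameter(s) (> 0).
#' @param major_nm Fitted-ellipse full major axis length(s) (> 0).
#' @return Dimensionless ratio.
#' @export
fmr <- function(feret_nm, major_nm) {
  if (any(feret_nm <= 0) || any(major_nm <= 0))
    abort("`feret_nm` and `major_nm` must be positive")
  feret_nm / major_nm
}

#' Reciprocal aspect ratio
#'
#' Ratio of the fitted ellipse's full minor to full major axis,
#' `RAR = b / a` in (0, 1]; 1 for a circle.
#'
#' @param major_nm,minor_nm Full axis lengths with `major_nm >= minor_nm > 0`.
#' @return Dimensionless ratio in (0, 1].
#' @export
rar <- function(major_nm, minor_nm) {
  if (any(minor_nm <= 0)) abort("axis lengths must be positive")
  if (any(minor_nm > major_nm))
    abort("`major_nm` must be >= `minor_nm`")
  minor_nm / major_nm
}

# 4 corner points of each pixel in a region; pixels given as 0-based
# (col, row) centers. Only boundary pixels contribute distinct extreme
# corners, but uniqueness handles the rest.
pixel_corners <- function(cols0, rows0) {
  x <- c(cols0 - 0.5, cols0 + 0.5, cols0 - 0.5, cols0 + 0.5)
  y <- c(rows0 - 0.5, rows0 - 0.5, rows0 + 0.5, rows0 + 0.5)
  pts <- unique(cbind(x, y))
  pts
}

# rotating calipers on a convex hull given in counter-clockwise order;
# returns squared diameter
calipers_sq <- function(hull) {
  n <- nrow(hull)
  if (n == 1) return(0)
  if (n == 2) return(sum((hull[1, ] - hull[2, ])^2))
  d2 <- function(i, j) sum((hull[i, ] - hull[j, ])^2)
  cross_edge <- function(i, k) {
    # area of triangle (p_i, p_{i+1}, p_k) * 2
    i2 <- i %% n + 1
    (hull[i2, 1] - hull[i, 1]) * (hull[k, 2] - hull[i, 2]) -
      (hull[i2, 2] - hull[i, 2]) * (hull[k, 1] - hull[i, 1])
  }
  best <- 0
  k <- 2
  for (i in seq_len(n)) {
    repeat {
      k2 <- k %% n + 1
      if (cross_edge(i, k2) > cross_edge(i, k)) k <- k2 else break
    }
    best <- max(best, d2(i, k), d2(i %% n + 1, k))
  }
  best
}

#' Maximum Feret (caliper) diameter of a pixel region
#'
#' The largest distance between two parallel tangent lines of the particle,
#' computed over the region's pixel-corner point set (each pixel contributes
#' its four corners, so a single pixel has Feret `sqrt(2)` pixel widths).
#' Implemented as convex hull + rotating calipers, which equals the
#' brute-force maximum pairwise corner distance.
#'
#' @param cols0,rows0 0-based column/row indices of the region's pixels.
#' @param nm_per_px Physical pixel size (nm).
#' @return Feret diameter in nm.
#' @export
feret_diameter <- function(cols0, rows0, nm_per_px = 1) {
  if (length(cols0) == 0) abort("empty region")
  pts <- pixel_corners(cols0, rows0)
  hi <- grDevices::chull(pts) # clockwise
  hull <- pts[rev(hi), , drop = FALSE] # counter-clockwise
  sqrt(calipers_sq(hull)) * nm_per_px
}

#' Moment-based ellipse fit of a pixel region
#'
#' Fits the ellipse having the same centroid and the same normalized second
#' central moments as the pixel region, each pixel treated as a unit square
#' (the 1/12 per-pixel variance term is included). Returns full axis
#' lengths, major first, and the major-axis orientation.
#'
#' For a rasterized ellipse the fitted axes recover the generating axes; a
#' square of side s yields the degenerate-direction result
#' `a = b = 2 s / sqrt(3)`.
#'
#' @param cols0,rows0 0-based pixel indices of the region.
#' @param nm_per_px Physical pixel size (nm).
#' @return `list(major_nm, minor_nm, orientation, degenerate)`; a
#'   single-pixel region returns both axes equal to the pixel size with
#'   `degenerate = TRUE`.
#' @export
fit_ellipse <- function(cols0, rows0, nm_per_px = 1) {
  n <- length(cols0)
  if (n == 0) abort("empty region")
  if (n == 1)
    return(list(major_nm = nm_per_px, minor_nm = nm_per_px,
                orientation = 0, degenerate = TRUE))
  xc <- mean(cols0); yc <- mean(rows0)
  m20 <- mean((cols0 - xc)^2) + 1 / 12
  m02 <- mean((rows0 - yc)^2) + 1 / 12
  m11 <- mean((cols0 - xc) * (rows0 - yc))
  common <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  l1 <- (m20 + m02) / 2 + common
  l2 <- (m20 + m02) / 2 - common
  list(major_nm = 4 * sqrt(l1) * nm_per_px,
       minor_nm = 4 * sqrt(max(l2, 0)) * nm_per_px,
       orientation = 0.5 * atan2(2 * m11, m20 - m02),
       degenerate = FALSE)
}

#' Measure every labeled region
#'
#' Computes the full per-particle descriptor set — pixel and physical area,
#' equivalent circular diameter, maximum Feret diameter, fitted-ellipse
#' axes, Feret major-axis ratio, reciprocal aspect ratio, centroid, and an
#' edge-contact flag — for each region, in label order. Degenerate regions
#' (single pixel) are flagged, never dropped.
#'
#' @param regions A `labeled_regions` object from [segment_particles()] or
#'   [label_components()].
#' @param nm_per_px Physical pixel size (nm).
#' @param source_id Identifier copied into every row.
#' @return A tibble with one row per region and columns `id`, `source_id`,
#'   `area_px`, `area_nm2`, `ecd_nm`, `feret_nm`, `major_nm`, `minor_nm`,
#'   `fmr`, `rar`, `cx_nm`, `cy_nm`, `touches_edge`, `degenerate`.
#' @examples
#' sc <- generate_scene(scene_spec(n_particles = 6, noise_sd = 0, seed = 3))
#' regs <- segment_particles(sc$image, seg_config(threshold_fraction = 0.02))
#' measure_particles(regs, sc$image$nm_per_px)
#' @export
measure_particles <- function(regions, nm_per_px, source_id = "image") {
  stopifnot(inherits(regions, "labeled_regions"))
  lm <- regions$label_map
  if (regions$n == 0)
    return(tibble(
      id = integer(), source_id = character(), area_px = integer(),
      area_nm2 = numeric(), ecd_nm = numeric(), feret_nm = numeric(),
      major_nm = numeric(), minor_nm = numeric(), fmr = numeric(),
      rar = numeric(), cx_nm = numeric(), cy_nm = numeric(),
      touches_edge = logical(), degenerate = logical()
    ))
  idx <- which(lm > 0L, arr.ind = TRUE)
  labs <- lm[lm > 0L]
  h <- nrow(lm); w <- ncol(lm)
  rows_by <- split(idx[, 1] - 1L, labs)
  cols_by <- split(idx[, 2] - 1L, labs)
  out <- vector("list", regions$n)
  for (i in seq_len(regions$n)) {
    r0 <- rows_by[[as.character(i)]]
    c0 <- cols_by[[as.character(i)]]
    npx <- length(r0)
    area_nm2 <- npx * nm_per_px^2
    ell <- fit_ellipse(c0, r0, nm_per_px)
    fer <- feret_diameter(c0, r0, nm_per_px)
    out[[i]] <- tibble(
      id = i, source_id = source_id,
      area_px = npx, area_nm2 = area_nm2,
      ecd_nm = ecd(area_nm2),
      feret_nm = fer,
      major_nm = ell$major_nm, minor_nm = ell$minor_nm,
      fmr = fmr(fer, ell$major_nm),
      rar = rar(ell$major_nm, ell$minor_nm),
      cx_nm = mean(c0) * nm_per_px, cy_nm = mean(r0) * nm_per_px,
      touches_edge = any(r0 == 0L | r0 == h - 1L | c0 == 0L | c0 == w - 1L),
      degenerate = ell$degenerate
    )
  }
  list_rbind(out)
}

#' Write a particle table as CSV
#'
#' Fixed header
#' `id,source_id,area_px,area_nm2,ecd_nm,feret_nm,major_nm,minor_nm,fmr,rar,cx_nm,cy_nm,touches_edge`.
#'
#' @param particles Tibble from [measure_particles()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_particles <- function(particles, path) {
  cols <- c("id", "source_id", "area_px", "area_nm2", "ecd_nm", "feret_nm",
            "major_nm", "minor_nm", "fmr", "rar", "cx_nm", "cy_nm",
            "touches_edge")
  write.csv(particles[, cols], path, row.names = FALSE)
  invisible(path)
}
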