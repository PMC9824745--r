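#' Specification of a synthetic micrograph scene
#'
#' Describes a field of dark, roughly convex nanoparticles on a textured
#' bright background, mimicking bright-field TEM of electron-dense metal
#' particles inside a cell. [generate_scene()] renders the scene and returns
#' exact per-particle ground truth, so every downstream stage can be tested
#' against known geometry.
#'
#' @param image_size_px Integer pair `c(width, height)` in pixels.
#' @param nm_per_px Physical pixel size in nanometres.
#' @param n_particles Number of particles to place (>= 0).
#' @param size_dist Equivalent-circular-diameter distribution. Either
#'   `list(family = "lognormal", median_nm =, sdlog =)` (draws are rejected
#'   outside `range_nm`) or `list(family = "fixed", ecd_nm =)`.
#' @param shape_regime `list(rar_mean =, rar_sd =, irregularity =)`:
#'   reciprocal aspect ratios are drawn from a normal rejected onto `(0, 1]`,
#'   and particle outlines are ellipses perturbed by a smooth low-order radial
#'   irregularity of the given relative amplitude. [au_regime()] and
#'   [eu_regime()] give the two presets (near-circular crystalline particles
#'   vs irregular amorphous ones).
#' @param background `list(mean =, gradient =, texture =)` in 8-bit units:
#'   mean level, amplitude of a low-frequency illumination ramp, and
#'   amplitude of mid-frequency texture blobs.
#' @param noise_sd Standard deviation of additive Gaussian noise (8-bit
#'   units), clipped to `[0, 255]`.
#' @param particle_level Mean particle intensity; particles are always
#'   rendered darker than the background.
#' @param allow_edge_overlap If `TRUE`, particles may be placed so that they
#'   overlap the image border (and are truncated); if `FALSE` (default) all
#'   particles are fully interior. Particle-particle overlaps are never
#'   generated.
#' @param scale_bar `list(length_nm =, on =)`; when on, a saturated bar of
#'   `round(length_nm / nm_per_px)` pixels is drawn near the bottom-left
#'   corner and its bounding box recorded.
#' @param range_nm Admissible ECD range in nm for lognormal draws.
#' @param seed Integer seed; identical specs give bit-identical scenes.
#'
#' @return A `scene_spec` list.
#' @seealso [generate_scene()], [render_particle()], [draw_scale_bar()]
#' @export
scene_spec <- function(image_size_px = c(512, 512),
                       nm_per_px = 0.5,
                       n_particles = 30,
                       size_dist = list(family = "lognormal",
                                        median_nm = 8, sdlog = 0.35),
                       shape_regime = au_regime(),
                       background = list(mean = 200, gradient = 15,
                                         texture = 8),
                       noise_sd = 4,
                       particle_level = 60,
                       allow_edge_overlap = FALSE,
                       scale_bar = list(length_nm = 100, on = TRUE),
                       range_nm = c(3, 35),
                       seed = 1L) {
  if (length(image_size_px) != 2 || any(image_size_px < 8))
    abort("`image_size_px` must be two integers >= 8")
  if (nm_per_px <= 0) abort("`nm_per_px` must be positive")
  if (n_particles < 0) abort("`n_particles` must be >= 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (!size_dist$family %in% c("lognormal", "fixed"))
    abort("`size_dist$family` must be 'lognormal' or 'fixed'")
  if (shape_regime$rar_mean <= 0 || shape_regime$rar_mean > 1)
    abort("`shape_regime$rar_mean` must lie in (0, 1]")
  structure(
    list(image_size_px = as.integer(image_size_px), nm_per_px = nm_per_px,
         n_particles = as.integer(n_particles), size_dist = size_dist,
         shape_regime = shape_regime, background = background,
         noise_sd = noise_sd, particle_level = particle_level,
         allow_edge_overlap = isTRUE(allow_edge_overlap),
         scale_bar = scale_bar, range_nm = range_nm,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Shape-regime presets
#'
#' `au_regime()` emulates near-circular crystalline particles (reciprocal
#' aspect ratio centered near 0.88 with small boundary irregularity);
#' `eu_regime()` emulates irregular amorphous particles (RAR centered near
#' 0.63, larger irregularity).
#'
#' @param rar_mean,rar_sd Mean and sd of the RAR draw (rejected onto (0, 1]).
#' @param irregularity Relative amplitude of the smooth radial perturbation.
#' @return A list usable as `shape_regime` in [scene_spec()].
#' @export
au_regime <- function(rar_mean = 0.88, rar_sd = 0.05, irregularity = 0.04) {
  list(rar_mean = rar_mean, rar_sd = rar_sd, irregularity = irregularity)
}

#' @rdname au_regime
#' @export
eu_regime <- function(rar_mean = 0.63, rar_sd = 0.10, irregularity = 0.18) {
  list(rar_mean = rar_mean, rar_sd = rar_sd, irregularity = irregularity)
}

# smooth radial perturbation profile: sum of harmonics k = 2..5 with random
# weights/phases, normalized so max |s(theta)| = 1
radial_profile <- function(theta, weights, phases) {
  s <- rep(0, length(theta))
  for (i in seq_along(weights))
    s <- s + weights[i] * cos((i + 1) * theta + phases[i])
  s / sum(abs(weights))
}

#' Render a single particle mask
#'
#' Rasterizes one particle — an ellipse optionally perturbed by a smooth
#' low-order radial irregularity — onto a canvas, returning the pixel mask
#' and the exact boundary polygon in physical units.
#'
#' @param canvas_size_px `c(width, height)` of the target canvas in pixels.
#' @param nm_per_px Physical pixel size (nm).
#' @param center_nm `c(x, y)` of the particle center in nm.
#' @param major_nm,minor_nm Full axis lengths of the base ellipse in nm
#'   (`major_nm >= minor_nm`).
#' @param orientation Major-axis angle in radians.
#' @param irregularity Relative amplitude of the radial perturbation
#'   (0 gives an exact ellipse).
#' @param n_vertices Polygon resolution.
#' @param seed Optional seed for the perturbation harmonics (reproducible
#'   outline); ignored when `irregularity == 0`.
#'
#' @return `list(mask = <logical matrix>, polygon = <n x 2 matrix, nm>)`.
#'   The mask is clipped to the canvas; the polygon is not.
#' @examples
#' p <- render_particle(c(64, 64), 1, c(32, 32), 20, 10)
#' sum(p$mask) # close to pi * 10 * 5
#' @export
render_particle <- function(canvas_size_px, nm_per_px, center_nm,
                            major_nm, minor_nm, orientation = 0,
                            irregularity = 0, n_vertices = 180,
                            seed = NULL) {
  if (minor_nm > major_nm) abort("`major_nm` must be >= `minor_nm`")
  if (minor_nm / nm_per_px <= 1)
    abort(sprintf("degenerate particle: minor axis %.2f px (<= 1 px)",
                  minor_nm / nm_per_px))
  a <- major_nm / 2
  b <- minor_nm / 2
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (irregularity > 0) {
    draw_coef <- function() {
      list(w = rnorm(4), ph = runif(4, 0, 2 * pi))
    }
    co <- if (is.null(seed)) draw_coef() else
      withr::with_seed(seed, draw_coef())
    r <- r * (1 + irregularity * radial_profile(theta, co$w, co$ph))
  }
  ang <- theta + orientation
  poly <- cbind(center_nm[1] + r * cos(ang), center_nm[2] + r * sin(ang))
  mask <- rasterize_polygon(poly, canvas_size_px, nm_per_px)
  list(mask = mask, polygon = poly)
}

# even-odd point-in-polygon over pixel centers in the polygon's bounding box
rasterize_polygon <- function(poly_nm, canvas_size_px, nm_per_px) {
  w <- canvas_size_px[1]; h <- canvas_size_px[2]
  mask <- matrix(FALSE, nrow = h, ncol = w)
  cmin <- max(0L, floor(min(poly_nm[, 1]) / nm_per_px))
  cmax <- min(w - 1L, ceiling(max(poly_nm[, 1]) / nm_per_px))
  rmin <- max(0L, floor(min(poly_nm[, 2]) / nm_per_px))
  rmax <- min(h - 1L, ceiling(max(poly_nm[, 2]) / nm_per_px))
  if (cmin > cmax || rmin > rmax) return(mask)
  cols <- cmin:cmax
  rows <- rmin:rmax
  px <- rep(cols, each = length(rows)) * nm_per_px
  py <- rep(rows, times = length(cols)) * nm_per_px
  inside <- logical(length(px))
  n <- nrow(poly_nm)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_nm[i, 1]; yi <- poly_nm[i, 2]
    xj <- poly_nm[j, 1]; yj <- poly_nm[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[cbind(rep(rows, times = length(cols)) + 1L,
             rep(cols, each = length(rows)) + 1L)] <- inside
  mask
}

# shoelace area and centroid of a closed polygon (vertices not repeated)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# bilinear upsample of a small random field to (h, w); values ~ [-1, 1]
texture_field <- function(h, w, cells = 16) {
  g <- matrix(rnorm(cells * cells), cells, cells)
  g <- g / max(abs(g))
  ri <- seq(1, cells, length.out = h)
  ci <- seq(1, cells, length.out = w)
  r0 <- pmin(floor(ri), cells - 1); c0 <- pmin(floor(ci), cells - 1)
  fr <- ri - r0; fc <- ci - c0
  G00 <- g[r0, c0, drop = FALSE]
  G10 <- g[r0 + 1, c0, drop = FALSE]
  G01 <- g[r0, c0 + 1, drop = FALSE]
  G11 <- g[r0 + 1, c0 + 1, drop = FALSE]
  FR <- matrix(fr, h, w)
  FC <- matrix(fc, h, w, byrow = TRUE)
  G00 * (1 - FR) * (1 - FC) + G10 * FR * (1 - FC) +
    G01 * (1 - FR) * FC + G11 * FR * FC
}

#' Generate a synthetic micrograph with exact ground truth
#'
#' Renders the scene described by a [scene_spec()]: a bright textured
#' background with an illumination ramp, dark particles with known geometry,
#' optional additive noise, and an optional scale bar. The same spec
#' (including its seed) always produces a bit-identical image and truth
#' table.
#'
#' @param spec A [scene_spec()].
#' @return `list(image = <image_grid>, truth = <tibble>)`. The truth tibble
#'   has one row per rendered particle with columns `id`, `true_area_nm2`,
#'   `true_ecd_nm`, `true_major_nm`, `true_minor_nm`, `true_rar`, `cx_nm`,
#'   `cy_nm`, `touches_edge` and a `polygon` list-column. The union of all
#'   particle pixels is attached to the image as attribute `"truth_mask"`;
#'   the scale-bar bounding box (if drawn) as `"scale_bar_px"`.
#'   `true_area_nm2` is the exact polygon (shoelace) area, so
#'   `true_ecd_nm = sqrt(4 * true_area_nm2 / pi)` holds exactly.
#' @examples
#' sc <- generate_scene(scene_spec(n_particles = 5, seed = 7))
#' nrow(sc$truth)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  w <- spec$image_size_px[1]; h <- spec$image_size_px[2]
  npx <- spec$nm_per_px

  # background: mean + illumination ramp + texture, in 8-bit units
  bg <- matrix(spec$background$mean, h, w)
  if (spec$background$gradient > 0) {
    dir <- runif(1, 0, 2 * pi)
    xs <- (seq_len(w) - 1) / max(w - 1, 1) - 0.5
    ys <- (seq_len(h) - 1) / max(h - 1, 1) - 0.5
    ramp <- outer(ys, xs, function(y, x) 2 * (cos(dir) * x + sin(dir) * y))
    bg <- bg + spec$background$gradient * ramp
  }
  if (spec$background$texture > 0)
    bg <- bg + spec$background$texture * texture_field(h, w)

  # particle parameter draws
  n <- spec$n_particles
  draws <- draw_particle_params(spec, n)

  # sequential placement with bounded retries; particles never overlap
  # each other (circumscribed-disc test with a 2 px gap)
  placed <- list()
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  for (i in seq_len(n)) {
    rmax_nm <- draws$major_nm[i] / 2 * (1 + spec$shape_regime$irregularity)
    ok <- FALSE
    for (try in seq_len(300)) {
      if (spec$allow_edge_overlap) {
        cx <- runif(1, 0, (w - 1) * npx)
        cy <- runif(1, 0, (h - 1) * npx)
      } else {
        m <- rmax_nm + 2 * npx
        if (2 * m >= (w - 1) * npx || 2 * m >= (h - 1) * npx)
          abort(sprintf("particle %d too large for the canvas", i))
        cx <- runif(1, m, (w - 1) * npx - m)
        cy <- runif(1, m, (h - 1) * npx - m)
      }
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
              radii + rmax_nm + 2 * npx)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      abort(sprintf(
        "could only place %d of %d particles; reduce n_particles or sizes",
        i - 1L, n))
    centers <- rbind(centers, c(cx, cy))
    radii <- c(radii, rmax_nm)
    placed[[i]] <- render_particle(
      c(w, h), npx, c(cx, cy),
      draws$major_nm[i], draws$minor_nm[i], draws$orientation[i],
      irregularity = spec$shape_regime$irregularity
    )
  }

  # compose: particles darker than background, with radial thickness
  # shading (dark core, brighter rim) plus a small per-particle offset
  img <- bg
  truth_mask <- matrix(FALSE, h, w)
  levels_p <- spec$particle_level + runif(n, -8, 8)
  shading_span <- 40
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    m <- placed[[i]]$mask
    idx <- which(m, arr.ind = TRUE)
    dx <- (idx[, 2] - 1) * npx - centers[i, 1]
    dy <- (idx[, 1] - 1) * npx - centers[i, 2]
    th <- draws$orientation[i]
    u <- (cos(th) * dx + sin(th) * dy) / (draws$major_nm[i] / 2)
    v <- (-sin(th) * dx + cos(th) * dy) / (draws$minor_nm[i] / 2)
    rho2 <- pmin(u^2 + v^2, 1)
    img[idx] <- levels_p[i] + shading_span * rho2
    truth_mask <- truth_mask | m
    poly <- placed[[i]]$polygon
    area <- polygon_area(poly)
    cen <- polygon_centroid(poly)
    touches <- any(m[1, ]) || any(m[h, ]) || any(m[, 1]) || any(m[, w])
    truth[[i]] <- tibble(
      id = i,
      true_area_nm2 = area,
      true_ecd_nm = sqrt(4 * area / pi),
      true_major_nm = draws$major_nm[i],
      true_minor_nm = draws$minor_nm[i],
      true_rar = draws$minor_nm[i] / draws$major_nm[i],
      cx_nm = cen[1], cy_nm = cen[2],
      touches_edge = touches,
      polygon = list(poly)
    )
  }
  truth <- if (n > 0) list_rbind(truth) else tibble(
    id = integer(), true_area_nm2 = numeric(), true_ecd_nm = numeric(),
    true_major_nm = numeric(), true_minor_nm = numeric(),
    true_rar = numeric(), cx_nm = numeric(), cy_nm = numeric(),
    touches_edge = logical(), polygon = list()
  )

  if (spec$noise_sd > 0)
    img <- img + rnorm(length(img), 0, spec$noise_sd)
  img <- pmin(pmax(round(img), 0), 255)

  out <- image_grid(img, npx, source_id = sprintf("synthetic-%d", spec$seed))
  if (isTRUE(spec$scale_bar$on))
    out <- draw_scale_bar(out, spec$scale_bar$length_nm)
  attr(out, "truth_mask") <- truth_mask
  list(image = out, truth = truth)
}

draw_particle_params <- function(spec, n) {
  sd_ <- spec$size_dist
  if (sd_$family == "fixed") {
    ecd <- rep(sd_$ecd_nm, n)
  } else {
    ecd <- numeric(0)
    while (length(ecd) < n) {
      cand <- rlnorm(n, meanlog = log(sd_$median_nm), sdlog = sd_$sdlog)
      cand <- cand[cand >= spec$range_nm[1] & cand <= spec$range_nm[2]]
      ecd <- c(ecd, cand)
    }
    ecd <- ecd[seq_len(n)]
  }
  reg <- spec$shape_regime
  rar <- numeric(0)
  while (length(rar) < n) {
    cand <- rnorm(n, reg$rar_mean, reg$rar_sd)
    rar <- c(rar, cand[cand > 0 & cand <= 1])
  }
  rar <- rar[seq_len(n)]
  # semi-axes preserving ECD-derived area and the drawn aspect ratio
  major <- ecd / sqrt(rar)
  minor <- ecd * sqrt(rar)
  list(major_nm = major, minor_nm = minor, rar = rar,
       orientation = runif(n, 0, pi))
}

#' Draw a scale bar onto an image
#'
#' Adds a solid saturated (intensity 255) horizontal bar of
#' `round(length_nm / nm_per_px)` pixels near the bottom-left corner. The
#' bar's bounding box is recorded in attribute `"scale_bar_px"` (1-based
#' `row0/row1/col0/col1`) so callers can crop it out before segmentation.
#'
#' @param image An [image_grid()].
#' @param length_nm Physical bar length in nm.
#' @return The image with the bar drawn.
#' @export
draw_scale_bar <- function(image, length_nm) {
  assert_image_grid(image)
  bar_px <- round(length_nm / image$nm_per_px)
  w <- ncol(image$pixels); h <- nrow(image$pixels)
  if (bar_px > w) abort(sprintf(
    "scale bar of %d px exceeds image width %d px", bar_px, w))
  margin <- max(2L, min(10L, h %/% 20))
  height <- max(2L, min(5L, h %/% 40))
  rows <- (h - margin - height + 1L):(h - margin)
  cols <- (margin + 1L):(margin + bar_px)
  if (max(cols) > w) cols <- seq_len(bar_px) # degenerate tiny margin case
  image$pixels[rows, cols] <- 255
  attr(image, "scale_bar_px") <- c(row0 = min(rows), row1 = max(rows),
                                   col0 = min(cols), col1 = max(cols))
  image
}

#' Write a scene to disk
#'
#' Saves the rendered image as 8-bit grayscale PNG (or TIFF by extension)
#' and the ground truth as CSV with the fixed header
#' `id,true_area_nm2,true_ecd_nm,true_major_nm,true_minor_nm,true_rar,cx_nm,cy_nm,touches_edge`.
#'
#' @param scene Result of [generate_scene()].
#' @param image_path Output image path (`.png` or `.tif`/`.tiff`).
#' @param truth_path Output CSV path.
#' @return Invisibly, the two paths.
#' @export
write_scene <- function(scene, image_path, truth_path) {
  write_image(scene$image, image_path)
  tr <- scene$truth
  tr$polygon <- NULL
  write.csv(tr, truth_path, row.names = FALSE)
  invisible(c(image_path, truth_path))
}
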