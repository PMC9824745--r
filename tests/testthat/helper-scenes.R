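# Shared fixtures: scenes are generated in code, never stored.

# a clean scene: flat background, no noise/texture/bar, fully interior
# disjoint particles -- the configuration where detection must be exact
clean_scene <- function(n = 10, seed = 1, size_px = c(512, 512),
                        nm_per_px = 0.5, shape = au_regime(),
                        size_dist = list(family = "lognormal",
                                         median_nm = 8, sdlog = 0.35)) {
  generate_scene(scene_spec(
    image_size_px = size_px, nm_per_px = nm_per_px, n_particles = n,
    size_dist = size_dist, shape_regime = shape,
    background = list(mean = 200, gradient = 0, texture = 0),
    noise_sd = 0, scale_bar = list(length_nm = 100, on = FALSE),
    seed = seed
  ))
}

# true foreground fraction of a generated scene
truth_fraction <- function(scene) mean(attr(scene$image, "truth_mask"))

# brute-force Feret oracle: max pairwise distance over all pixel corners
bf_feret <- function(cols0, rows0, nm_per_px = 1) {
  x <- c(cols0 - 0.5, cols0 + 0.5, cols0 - 0.5, cols0 + 0.5)
  y <- c(rows0 - 0.5, rows0 - 0.5, rows0 + 0.5, rows0 + 0.5)
  pts <- unique(cbind(x, y))
  max(dist(pts)) * nm_per_px
}

# random small pixel set (not necessarily connected; Feret is defined on
# any point set)
random_mask_pixels <- function(max_px = 400) {
  n <- sample(1:max_px, 1)
  side <- sample(5:25, 1)
  cells <- sample(side * side, min(n, side * side))
  list(cols0 = (cells - 1) %% side, rows0 = (cells - 1) %/% side)
}

# greedy nearest-centroid matching of measured particles to ground truth
match_to_truth <- function(particles, truth) {
  stopifnot(nrow(particles) == nrow(truth))
  d <- outer(particles$cx_nm, truth$cx_nm, "-")^2 +
    outer(particles$cy_nm, truth$cy_nm, "-")^2
  idx <- apply(d, 1, which.min)
  stopifnot(!anyDuplicated(idx))
  truth[idx, ]
}

# rasterize one axis-aligned disk directly (independent of the generator)
disk_pixels <- function(cx, cy, radius_px, size = 64) {
  g <- expand.grid(col = 0:(size - 1), row = 0:(size - 1))
  keep <- (g$col - cx)^2 + (g$row - cy)^2 <= radius_px^2
  list(cols0 = g$col[keep], rows0 = g$row[keep])
}
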