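---
title: "Nanoparticle morphometry from electron micrographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanoparticle morphometry from electron micrographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomorph)
```

## The problem

Microorganisms such as filamentous cyanobacteria can biosorb dissolved metal
ions (gold, europium, other rare earths) and reduce them intracellularly to
nanoparticles. Whether such bioproduction can deliver particles of a *chosen*
size and shape is assessed by imaging resin-embedded, ultrathin-sectioned
cells in bright-field TEM and quantifying the particles: how many formed, how
large they are, and how round they are, as a function of incubation time.

nanomorph implements that quantification as a reproducible pipeline:

1. **Segmentation** — detect electron-dense (dark) particles in an 8-bit
   micrograph.
2. **Morphometry** — measure each particle: area, equivalent circular
   diameter, maximum Feret diameter, moment-fitted ellipse axes, and two
   shape ratios.
3. **Distribution statistics** — particle-size distributions (PSDs),
   mean/SE/percentile summaries, cumulative frequencies, and a six-class
   roundness classification.
4. **Cell accounting** — convert measured cell section areas into sampled
   volumes, normalize particle counts to a standard 1.00 µm³, and compare
   local 500 × 500 nm² regions of interest for hotspots.
5. **Synthetic scenes** — generate micrograph-like images with exact
   per-particle ground truth, so every stage above is testable without
   access to the original TEM data.

## Segmentation model

The detection workflow mirrors the manual ImageJ procedure used in practice:

* **Preprocessing.** Optional 3×3 uniform mean smoothing followed by the
  classic 3×3 sharpen kernel (center 12, all eight neighbours −1, divided
  by 4; the kernel sums to 1 so flat fields are unchanged). Borders are
  edge-replicated; output is rounded and clipped to [0, 255].
* **Percentile thresholding.** The user supplies the *fraction of image
  pixels* that should become foreground (e.g. 0.002 for a published
  "threshold 0.2 %"). The largest gray cutoff whose cumulative histogram
  fraction does not exceed the request is chosen, and all pixels at or
  below it are selected. This transfers across images of different overall
  brightness, which a raw gray-level cutoff would not, and it is monotone:
  raising the fraction can only grow the mask.
* **Labeling.** Connected components under 8-connectivity by default
  (configurable to 4), via a two-pass union-find labeler in C++.
* **Size filtering.** An inclusive pixel-count range (e.g. 5–500 px, or
  10–inf) removes background specks at the low end and staining artifacts
  or organelles at the high end.
* **Edge exclusion.** Any region owning a pixel in the first/last row or
  column is removed — truncated particles would bias the size statistics.

Fused particle pairs are deliberately *not* split (no watershed): the
reference workflow counts a fused pair as one particle, and the synthetic
generator can reproduce that failure mode for study.

## Per-particle descriptors

For a region of $n$ pixels at scale $s$ nm/px, with area $A = n s^2$:

* **ECD** (equivalent circular diameter): $\mathrm{ECD} = \sqrt{4A/\pi}$ —
  the diameter of the circle of equal area.
* **Feret diameter** $D_f$: the maximum caliper distance across the
  particle, computed over the region's pixel *corners* (each pixel
  contributes its four corners), via convex hull + rotating calipers. The
  corner convention means a single pixel has $D_f = \sqrt{2}\,s$ rather
  than 0, and matches caliper semantics on the pixel footprint.
* **Fitted ellipse** $(a, b)$: the ellipse with the same centroid and the
  same normalized second central moments as the pixel region, each pixel
  treated as a unit square (the $1/12$ variance term). Full axis lengths
  are reported. For a rasterized ellipse this recovers the generating axes
  to well under 2 %; for a square of side $s$ it gives
  $a = b = 2s/\sqrt{3}$. No equal-area rescaling is applied; the aspect
  ratio is identical either way, and only markedly non-elliptical outlines
  change their Feret ratio by a few percent under the alternative
  convention.
* **FMR** $= D_f / a$: 1 for an ideal ellipse, larger for angular or
  irregular outlines (a square gives $\sqrt{6}/2 \approx 1.22$).
* **RAR** $= b / a \in (0, 1]$: 1 for a circle, small for elongated
  particles.

A population's mean ECD is the *mean of per-particle ECDs*, never the ECD
of the mean area. ECD is concave in area, so the two differ (Jensen's
inequality); published mean-area/mean-ECD pairs are only consistent with
the per-particle average, and the package preserves that convention.

## Roundness classification

RAR values are assigned to six classes — very angular [0.12, 0.17),
angular [0.17, 0.25), sub-angular [0.25, 0.35), sub-rounded [0.35, 0.49),
rounded [0.49, 0.70), very rounded [0.70, 1.00] — left-closed intervals,
the last closed, partitioning [0.12, 1]. Values below 0.12 (beyond the
scale of the classification) are assigned to very angular with a warning.
The boundary rule is this package's convention; published tables print
touching interval endpoints without stating one.

## Cell accounting

An ultrathin section of thickness $t$ (default 60 nm) samples a volume
$V = A_{\mathrm{cell}} \cdot t / 1000$ µm³ from a cell of measured section
area $A_{\mathrm{cell}}$ µm². Counts are normalized to particles per
1.00 µm³ ($N/V$), which makes cells of different size comparable;
`percent_change()` and `coverage_fraction()` complete the bookkeeping
(growth/decline between time points, and what fraction of a cell's
particles a set of high-resolution fields captured). Cell areas are
supplied by the user (measured manually, as in the reference workflow);
automatic cell segmentation is out of scope.

For local analysis, `local_psd()` crops square ROIs (default 500 nm side),
runs the full detection workflow independently in each — including edge
exclusion at ROI borders, exactly as at image borders — and
`compare_rois()` reports each ROI's deviation from the mean of the
others. A ROI is flagged as a candidate hotspot when its count deviates
by more than twice the standard deviation of the *other* ROIs. The
leave-one-out form is deliberate: with the typical five ROIs, an extreme
region inflates a pooled standard deviation enough to hide itself (the
within-sample z-score is bounded by $(k-1)/\sqrt{k} \approx 1.79$ at
$k = 5$), whereas the leave-one-out rule fires on genuine dense regions
and stays quiet on ordinary Poisson scatter.

Each ROI may carry its own threshold. This matters: the percentile
threshold adapts to each window's content, so reusing one global fraction
would *normalize away* density differences between windows. Supplying
per-window thresholds (as the reference analyses do) preserves them.

## The synthetic scene generator

`generate_scene()` emulates the imaging situation, not the physics: dark,
roughly convex particles on a bright, textured background.

* **Sizes.** ECDs are drawn lognormal (default median 8 nm, sdlog 0.35,
  rejected outside 3–35 nm — the range where such bioproduced particles
  are observed) or fixed.
* **Shapes.** Each particle is an ellipse with RAR drawn from a normal
  rejected onto (0, 1], optionally perturbed by a smooth radial
  irregularity (harmonics 2–5, normalized, relative amplitude as
  configured). Two presets bracket the observed regimes:
  `au_regime()` (RAR ~ N(0.88, 0.05), irregularity 0.04) for near-circular
  crystalline particles and `eu_regime()` (RAR ~ N(0.63, 0.10),
  irregularity 0.18) for irregular amorphous ones.
* **Intensity.** Background = mean level (default 200) + low-frequency
  illumination ramp (±15) + mid-frequency texture (±8), in 8-bit units.
  Particles are rendered at a dark base level (default 60 ± 8 per
  particle) with *radial thickness shading* — darker core, brighter rim —
  mimicking mass-thickness contrast. The shading is load-bearing for
  robustness: it makes detection stable under a ±20 % mis-set threshold
  (the threshold band trims rims rather than dropping whole particles).
  Additive Gaussian noise (default sd 4) is clipped to [0, 255].
* **Placement.** Particles never overlap one another (circumscribed-disc
  test with a 2 px gap, bounded retries with an explicit error naming the
  achieved count when a spec is overcrowded). `allow_edge_overlap = TRUE`
  lets particles overlap the image border, producing the edge-truncated
  particles the edge filter must remove. Fused pairs can be composed
  explicitly via `render_particle()`.
* **Ground truth.** Per particle: the exact boundary polygon, its shoelace
  area (so `true_ecd = sqrt(4*area/pi)` holds exactly), the generating
  ellipse axes and RAR, centroid, and an edge flag. The union foreground
  mask rides along as an attribute, and an optional saturated scale bar of
  `round(length_nm / nm_per_px)` px is drawn and recorded for the
  calibration path.

What the generator does **not** emulate: contrast-transfer-function
effects, defocus, cell ultrastructure (thylakoids, ribosomes) beyond
generic texture, or detector noise statistics (none are published for the
reference images). Passing tests therefore demonstrate correctness of the
*measurement chain* on controlled inputs, not segmentation robustness on
arbitrary real micrographs — on real data, thresholds and size ranges
still require the same per-image judgment they always have.

## Numerical choices

* Percentiles: linear interpolation between closest order statistics
  (`quantile(type = 7)`); the 10/25/75/90 set matches the whisker/box
  convention of the reference plots.
* Standard error: sample SD (n−1) over √n; reported as the SE of the mean.
* Histogram bins: left-closed right-open, anchored at 0 by default;
  conventional widths 10 nm² (area), 1 nm (ECD), 0.05 (RAR/FMR), 50 nm²
  for local ROI area classes. All configurable.
* Reported precision follows field convention: lengths to 0.1 nm, ratios
  to 0.01.
* Single-pixel regions get both ellipse axes set to the pixel size and a
  `degenerate` flag instead of an error; batch measurement never aborts.
* Coordinates are 0-based pixel centers; physical positions in nm from the
  top-left pixel center. Crops record their offset so centroids map back.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script validate on: exact-recovery
scenes of 30 particles (768² px), a 500-particle lognormal field
(1250² px) for distribution-mean recovery within 2 SE, 80-particle noisy
regime scenes (1000² px) for the shape-class contrast, 200 random masks
for the Feret caliper-vs-brute-force equivalence, and a 10⁻⁴-step grid for
the classification partition. These sizes give stable statistics while
keeping the whole suite fast enough to run routinely.

## Known limitations

* No watershed splitting: touching particles count as one, matching the
  reference convention but biasing PSD tails when agglomeration is heavy.
* No stereological correction for particles cut by the section surfaces;
  volume normalization assumes the printed 60 nm thickness.
* The percentile-threshold interpretation of published per-image
  "threshold %" values is a documented convention of this package; the
  original analyses may have used a manual gray-level window.
* Shape descriptors are limited to $A$, $D_f$, $a$, $b$ and their two
  ratios; no convexity, solidity or perimeter-based circularity.

## A worked example

```{r, eval = FALSE}
library(nanomorph)

sc <- generate_scene(scene_spec(n_particles = 40, seed = 42,
                                shape_regime = eu_regime()))
regs <- segment_particles(
  sc$image, seg_config(threshold_fraction = 0.01, min_area_px = 10),
  verbose = TRUE)
pt <- measure_particles(regs, sc$image$nm_per_px)

glance(psd_histogram(pt$ecd_nm, 1, metric_name = "ECD [nm]"))
class_fractions(pt)
autoplot(psd_histogram(pt$area_nm2, 10, metric_name = "area [nm2]"))
```
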