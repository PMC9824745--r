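# nanomorph

Quantitative morphometry of bioproduced nanoparticles in transmission
electron micrographs.

Microorganisms — notably filamentous cyanobacteria — can take up dissolved
metal ions (Au³⁺, Eu³⁺ and other rare earths) and reduce them to
intracellular nanoparticles. Judging whether such bioproduction yields
particles of controlled size and shape requires measuring them: counting
particles per cell volume, building particle-size distributions (PSDs),
and classifying particle roundness, from bright-field TEM images of
ultrathin cell sections. nanomorph packages that digital analysis as a
tested, scriptable pipeline for microscopists and bioprocess researchers,
together with a synthetic micrograph generator that provides exact ground
truth for validating every stage.

## The measurements

For each detected particle region of pixel area *A* (converted to nm² via
the pixel calibration):

- **ECD** — equivalent circular diameter, `ECD = sqrt(4A/π)`: the diameter
  of the circle of equal area.
- **D_f** — maximum Feret (caliper) diameter, computed by convex hull +
  rotating calipers over the region's pixel corners.
- **a, b** — full major and minor axes of the ellipse with the same
  normalized second central moments as the pixel region.
- **FMR** — Feret major-axis ratio `D_f / a` (1 for an ideal ellipse;
  larger for angular outlines).
- **RAR** — reciprocal aspect ratio `b / a ∈ (0, 1]` (1 for a circle).

RAR values map to six roundness classes (very angular 0.12–0.17, angular
0.17–0.25, sub-angular 0.25–0.35, sub-rounded 0.35–0.49, rounded
0.49–0.70, very rounded 0.70–1.00). Particle counts are normalized per
standard 1.00 µm³ of cell using the section-area × 60 nm slice-thickness
volume, and square regions of interest (500 × 500 nm²) can be analyzed
independently and compared for local hotspots.

Detection follows the classic ImageJ-style workflow: optional 3×3
smoothing and sharpening, a percentile threshold (the darkest fraction of
pixels, so settings transfer across images of different brightness),
8-connected component labeling, an inclusive pixel size range, and
exclusion of border-touching particles.

## A worked example

```r
library(nanomorph)

# a synthetic micrograph: 40 near-circular particles, known ground truth
sc <- generate_scene(scene_spec(n_particles = 40,
                                image_size_px = c(800, 800),
                                nm_per_px = 0.5, seed = 42))

regs <- segment_particles(
  sc$image,
  seg_config(threshold_fraction = 0.017, min_area_px = 10),
  verbose = TRUE)
#> [synthetic-42] label: kept 40, removed 0
#> [synthetic-42] size_filter: kept 40, removed 0
#> [synthetic-42] edge_exclude: kept 40, removed 0

pt <- measure_particles(regs, sc$image$nm_per_px)
pt[1:4, c("id", "area_nm2", "ecd_nm", "feret_nm", "fmr", "rar")]
#>      id area_nm2 ecd_nm feret_nm   fmr   rar
#> 1     1     35.2   6.70     7.83  1.08 0.859
#> 2     2    138.   13.3     14.4   1.04 0.915
#> 3     3     88.2  10.6     12.0   1.07 0.886
#> 4     4     32.5   6.43     7.52  1.07 0.850

glance(psd_histogram(pt$ecd_nm, 1, metric_name = "ecd_nm"))[, 1:8]
#>   metric     n  mean    se   p10   p25   p75   p90
#> 1 ecd_nm    40  8.55 0.584  5.38  6.02  9.80  13.3

class_fractions(pt)
#>   class        count percent
#> 1 very_angular     0       0
#> 2 angular          0       0
#> 3 sub_angular      0       0
#> 4 sub_rounded      0       0
#> 5 rounded          0       0
#> 6 very_rounded    40     100
```

All 40 planted particles are recovered; the mean ECD of 8.55 nm (SE 0.58)
agrees with the generator's lognormal median of 8 nm, and the
near-circular regime lands entirely in the "very rounded" class. Tying
the counts to a cell: a 20.17 µm² cell section sampled by a 60 nm slice
gives a 1.21 µm³ volume,

```r
cell_summary("cell-1", cell_area_um2 = 20.17, n_particles = 40)
#>   cell_id cell_area_um2 slice_thickness_nm cell_volume_um3 n_particles normalized_count
#> 1 cell-1          20.2                 60            1.21          40             33.1
```

i.e. 33 particles per standard µm³ of cell. `psd_histogram()` objects have
`tidy()`/`glance()` methods and `autoplot()`; `run_pipeline()` drives the
whole analysis (whole-cell or local-ROI mode) from a YAML config and
writes particle tables, PSD summaries, class fractions and a run manifest
as CSV/JSON. A thin command-line wrapper lives in `inst/cli/nanomorph`.

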