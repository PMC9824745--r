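#' The six roundness classes
#'
#' Interval assignment of reciprocal aspect ratio (RAR) values to six shape
#' classes, from very angular to very rounded. Intervals are left-closed,
#' right-open, except the last which is closed at 1.00; together they
#' partition `[0.12, 1.00]`.
#'
#' @return A tibble with columns `class`, `rar_low`, `rar_high`.
#' @export
shape_classes <- function() {
  tibble(
    class = factor(
      c("very_angular", "angular", "sub_angular",
        "sub_rounded", "rounded", "very_rounded"),
      levels = c("very_angular", "angular", "sub_angular",
                 "sub_rounded", "rounded", "very_rounded")
    ),
    rar_low = c(0.12, 0.17, 0.25, 0.35, 0.49, 0.70),
    rar_high = c(0.17, 0.25, 0.35, 0.49, 0.70, 1.00)
  )
}

#' Classify particles by reciprocal aspect ratio
#'
#' Maps each RAR in (0, 1] to one of the six roundness classes (see
#' [shape_classes()]). Boundary rule: intervals are left-closed right-open,
#' the last class `[0.70, 1.00]` closed. Values in (0, 0.12) fall below the
#' scale and are assigned `very_angular` with a warning.
#'
#' @param rar_value Numeric vector of RAR values in (0, 1].
#' @return Factor with the six class levels, same length as the input.
#' @examples
#' classify_rar(c(0.63, 0.88, 1.0))
#' @export
classify_rar <- function(rar_value) {
  if (any(rar_value <= 0 | rar_value > 1))
    abort("RAR values must lie in (0, 1]")
  cls <- shape_classes()
  idx <- findInterval(rar_value, cls$rar_low)
  if (any(idx == 0)) {
    warn(sprintf("%d RAR value(s) below 0.12 assigned to 'very_angular'",
                 sum(idx == 0)))
    idx[idx == 0] <- 1L
  }
  factor(as.character(cls$class)[idx], levels = levels(cls$class))
}

#' Per-class particle fractions
#'
#' Counts particles in each of the six roundness classes and expresses them
#' as percentages of the total (summing to 100).
#'
#' @param particles Tibble with a `rar` column (e.g. from
#'   [measure_particles()]), or a bare numeric vector of RAR values.
#' @return A tibble with columns `class`, `count`, `percent` (six rows).
#' @export
class_fractions <- function(particles) {
  r <- if (is.numeric(particles)) particles else particles$rar
  if (length(r) == 0) abort("no particles to classify")
  cl <- classify_rar(r)
  tab <- table(cl)
  tibble(class = factor(names(tab), levels = levels(cl)),
         count = as.integer(tab),
         percent = 100 * as.integer(tab) / length(r))
}

#' Mean, standard error and percentiles of a metric
#'
#' Arithmetic mean, standard error of the mean (sample sd over sqrt(n)),
#' and the 10/25/75/90 percentiles by linear interpolation between closest
#' order statistics (the quartile whiskers and boxes of the package's PSD
#' plots).
#'
#' @param values Numeric vector, `n >= 1`.
#' @return One-row tibble `n`, `mean`, `se`, `p10`, `p25`, `p75`, `p90`;
#'   `se` is `NA` for `n = 1`.
#' @export
summary_stats <- function(values) {
  n <- length(values)
  if (n == 0) abort("`values` must be non-empty")
  q <- quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  tibble(n = n, mean = mean(values),
         se = if (n >= 2) sd(values) / sqrt(n) else NA_real_,
         p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4])
}

#' Cumulative frequency curve
#'
#' Sorted values against cumulative percentage of particles at or below
#' each value; monotone non-decreasing and ending at exactly 100%.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return Tibble with columns `value`, `cum_pct`.
#' @export
cumulative_frequency <- function(values) {
  n <- length(values)
  if (n == 0) abort("`values` must be non-empty")
  tibble(value = sort(values), cum_pct = 100 * seq_len(n) / n)
}

#' Particle-size-distribution summary
#'
#' Histogram of one particle metric with left-closed right-open bins of
#' fixed width anchored at `origin` (default 0), plus the mean, standard
#' error, percentile, and dominant-bin summaries used throughout the
#' package's distribution reports.
#'
#' @param values Numeric vector of the metric (non-empty).
#' @param bin_width Bin width in metric units (> 0). Conventional defaults:
#'   10 nm^2 for areas, 1 nm for ECDs, 0.05 for the RAR/FMR shape ratios.
#' @param origin Left edge of the bin lattice (default 0).
#' @param metric_name Label carried into tidies and plots.
#' @return A `psd_summary` object; see [tidy.psd_summary()] /
#'   [glance.psd_summary()] for tabular views.
#' @examples
#' p <- psd_histogram(c(1, 1, 2), bin_width = 1)
#' glance(p)
#' @export
psd_histogram <- function(values, bin_width, origin = 0,
                          metric_name = "metric") {
  if (length(values) == 0) abort("`values` must be non-empty")
  if (bin_width <= 0) abort("`bin_width` must be positive")
  lo <- origin + floor((min(values) - origin) / bin_width) * bin_width
  hi <- origin + (floor((max(values) - origin) / bin_width) + 1) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  # left-closed right-open bins
  idx <- pmin(findInterval(values, edges), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  dom <- which.max(counts)
  stats <- summary_stats(values)
  structure(
    list(metric_name = metric_name, bin_edges = edges, counts = counts,
         n_total = length(values), mean = stats$mean, se = stats$se,
         percentiles = c(p10 = stats$p10, p25 = stats$p25,
                         p75 = stats$p75, p90 = stats$p90),
         dominant_bin = list(low = edges[dom], high = edges[dom + 1],
                             fraction = counts[dom] / length(values)),
         values = values),
    class = "psd_summary"
  )
}

#' @export
print.psd_summary <- function(x, ...) {
  cat(sprintf(
    "<psd_summary> %s: n = %d, mean = %.3g, SE = %.3g\n",
    x$metric_name, x$n_total, x$mean, x$se))
  cat(sprintf("  dominant bin [%.3g, %.3g): %.1f%%\n",
              x$dominant_bin$low, x$dominant_bin$high,
              100 * x$dominant_bin$fraction))
  invisible(x)
}

#' Tidy a PSD summary into a per-bin tibble
#'
#' @param x A `psd_summary`.
#' @param ... Unused.
#' @return Tibble with `bin_low`, `bin_high`, `count`, `fraction`.
#' @export
tidy.psd_summary <- function(x, ...) {
  k <- length(x$counts)
  tibble(bin_low = x$bin_edges[seq_len(k)],
         bin_high = x$bin_edges[seq_len(k) + 1],
         count = x$counts,
         fraction = x$counts / x$n_total)
}

#' One-row summary of a PSD
#'
#' @param x A `psd_summary`.
#' @param ... Unused.
#' @return One-row tibble with n, mean, SE, percentiles and dominant bin.
#' @export
glance.psd_summary <- function(x, ...) {
  tibble(metric = x$metric_name, n = x$n_total, mean = x$mean, se = x$se,
         p10 = x$percentiles[["p10"]], p25 = x$percentiles[["p25"]],
         p75 = x$percentiles[["p75"]], p90 = x$percentiles[["p90"]],
         dominant_low = x$dominant_bin$low,
         dominant_high = x$dominant_bin$high,
         dominant_fraction = x$dominant_bin$fraction)
}

#' Turn a result object into a tidy tibble
#'
#' @param x An object (e.g. a `psd_summary`).
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model/result summary
#'
#' @param x An object (e.g. a `psd_summary`).
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Write a PSD summary to disk
#'
#' The histogram as CSV (`bin_low,bin_high,count`) with a JSON sidecar of
#' the summary statistics next to it (same path, `.json` extension).
#'
#' @param x A `psd_summary`.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_psd <- function(x, path) {
  td <- tidy(x)
  write.csv(td[, c("bin_low", "bin_high", "count")], path,
            row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(as.list(glance(x)), side, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
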