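#' Clean raw interburst-interval samples
#'
#' Intervals below the cutoff are interflash gaps within a burst, not
#' interburst intervals, and are removed. Order is preserved; the number
#' removed is recorded in the `n_removed` attribute.
#'
#' @param raw Numeric vector of durations (seconds), or a data frame with
#'   an `ibi_s` column.
#' @param cutoff Minimum admissible interval in seconds (default 2.0).
#' @param label Free-text provenance tag.
#' @return A tibble of class `ibi_samples` with column `ibi_s` and
#'   attributes `n_removed` and `label`.
#' @export
#' @examples
#' clean_ibi_samples(c(1.0, 5.7, 30.0))
clean_ibi_samples <- function(raw, cutoff = 2.0, label = "samples") {
  values <- if (is.data.frame(raw)) {
    if (!"ibi_s" %in% names(raw)) abort("Data frame input needs an `ibi_s` column.")
    raw$ibi_s
  } else {
    as.numeric(raw)
  }
  if (length(values) == 0) abort("No samples supplied.")
  if (any(!is.finite(values))) abort("Samples must be finite numbers.")
  keep <- values >= cutoff
  if (!any(keep)) {
    abort(sprintf("All %d samples fall below the %.3g s cutoff: empty after cleaning.",
                  length(values), cutoff))
  }
  out <- tibble::tibble(ibi_s = values[keep])
  structure(out,
    n_removed = sum(!keep), cutoff = cutoff, label = label,
    class = c("ibi_samples", class(out))
  )
}

#' Histogram-spline envelope of an interval distribution
#'
#' Implements the envelope protocol for turning a cleaned sample of
#' interburst intervals into a smooth gridded density:
#' \enumerate{
#'   \item a density histogram with `n_bins` uniform bins on
#'     `[min(x), max(x)]` (right-closed, so the maximum is included);
#'   \item a natural cubic spline through the (bin center, density height)
#'     pairs;
#'   \item evaluation on a fine grid (`grid_step`) over the sample range,
#'     negative spline excursions clipped to zero;
#'   \item zero-padding on `[0, min(x))` — intervals shorter than the
#'     observed minimum are physiologically excluded;
#'   \item renormalization so the trapezoid integral is exactly 1.
#' }
#'
#' @param samples An `ibi_samples` tibble (see [clean_ibi_samples()]) or a
#'   numeric vector of cleaned intervals.
#' @param n_bins Number of uniform histogram bins (default 50).
#' @param grid_step Output grid resolution in seconds (default 0.1).
#' @return An [ibi_density] with `t_min = min(x)`, `t_max = max(x)` and an
#'   extra attribute `bin_width = (max - min) / n_bins`.
#' @export
build_envelope <- function(samples, n_bins = 50, grid_step = 0.1) {
  x <- if (is.data.frame(samples)) samples$ibi_s else as.numeric(samples)
  stopifnot(n_bins >= 2, grid_step > 0)
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) abort("Degenerate samples: min == max, no histogram possible.")
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = breaks, include.lowest = TRUE,
                      right = TRUE, plot = FALSE)
  env <- splinefun(h$mids, h$density, method = "natural")
  t_s <- seq(0, ceiling(hi / grid_step) * grid_step, by = grid_step)
  dens <- numeric(length(t_s))
  on_support <- t_s >= lo & t_s <= hi
  dens[on_support] <- pmax(env(t_s[on_support]), 0)
  out <- ibi_density(t_s, dens, t_min = lo, t_max = hi, label = "envelope")
  attr(out, "bin_width") <- (hi - lo) / n_bins
  out
}

#' Sample intervals from a gridded density
#'
#' Inverse-CDF sampling on the piecewise-linear cumulative distribution of
#' the grid: continuous draws, always within `[t_min, t_max]`.
#'
#' @param density An [ibi_density].
#' @param n Number of draws (`n >= 1`).
#' @param seed Optional integer seed; identical seeds give identical draws.
#' @return Numeric vector of `n` intervals in seconds.
#' @export
sample_ibi <- function(density, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- reduced_cdf(density)
  stats::approx(r$cdf, r$grid, xout = runif(n), ties = "ordered")$y
}
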