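#' Detect collective bursts in a flash series
#'
#' Flashes are pooled over all agents, ordered by start time, and grouped
#' into temporal connected components: a flash joins the current burst iff
#' its start is within `gap` seconds of the previous flash's start. The
#' burst's time is the start of its first flash.
#'
#' @param flashes A [flash_series()] (or any data frame with `t_start`).
#' @param gap Gap threshold in seconds (default 2.0).
#' @return A tibble of class `burst_train` with column `burst_start`
#'   (strictly increasing; consecutive entries more than `gap` apart) and
#'   attribute `gap`.
#' @export
#' @examples
#' fs <- flash_series(c(1, 2, 1, 2), c(0, 0.4, 12.1, 12.6), c(0.3, 0.7, 12.4, 12.9))
#' detect_bursts(fs)
detect_bursts <- function(flashes, gap = 2.0) {
  if (nrow(flashes) == 0) abort("Empty flash series: nothing to detect.")
  starts <- sort(flashes$t_start)
  new_burst <- c(TRUE, diff(starts) > gap)
  out <- tibble::tibble(burst_start = starts[new_burst])
  structure(out,
    gap = gap, n_flashes = length(starts),
    class = c("burst_train", class(out))
  )
}

#' Interburst intervals of a burst train
#'
#' First differences of the burst start times: the time from the first
#' flash of one collective burst to the first flash of the next.
#'
#' @param train A `burst_train` from [detect_bursts()].
#' @return A tibble of class `ibi_set` with column `interval_s` and
#'   attribute `definition = "burst_first_to_first"`.
#' @export
interburst_intervals <- function(train) {
  if (nrow(train) < 2) abort("Need at least two bursts to form intervals.")
  out <- tibble::tibble(interval_s = diff(train$burst_start))
  structure(out,
    definition = "burst_first_to_first",
    class = c("ibi_set", class(out))
  )
}

#' Flash-to-flash intervals of a pooled series
#'
#' First differences of all flash start times pooled over agents,
#' regardless of burst membership. Zero intervals (simultaneous starts)
#' are retained: they encode synchrony.
#'
#' @param flashes A [flash_series()].
#' @return A tibble of class `ibi_set` with column `interval_s` and
#'   attribute `definition = "flash_to_flash"`.
#' @export
flash_to_flash_intervals <- function(flashes) {
  if (nrow(flashes) < 2) abort("Need at least two flashes to form intervals.")
  out <- tibble::tibble(interval_s = diff(sort(flashes$t_start)))
  structure(out,
    definition = "flash_to_flash",
    class = c("ibi_set", class(out))
  )
}

#' Summary statistics of an interval sample
#'
#' The mode is the centre of the highest histogram bin (bins of width
#' `bin_width` anchored at 0; ties resolve to the smallest centre); mean
#' and standard deviation are plain sample statistics.
#'
#' @param samples An `ibi_set` (or any data frame with `interval_s`, or a
#'   numeric vector).
#' @param bin_width Histogram bin width in seconds (default 0.5).
#' @return A list with `mode_s`, `mean_s`, `sd_s`, `n`, and `histogram`
#'   (a tibble of bin centres and counts).
#' @export
summarize_intervals <- function(samples, bin_width = 0.5) {
  x <- if (is.data.frame(samples)) samples$interval_s else as.numeric(samples)
  if (length(x) == 0) abort("No intervals to summarize.")
  stopifnot(bin_width > 0)
  bin <- floor(x / bin_width)
  counts <- dplyr::count(tibble::tibble(bin = bin), .data$bin)
  hist_tbl <- tibble::tibble(
    center_s = (counts$bin + 0.5) * bin_width,
    count = counts$n
  )
  list(
    mode_s = hist_tbl$center_s[which.max(hist_tbl$count)],
    mean_s = mean(x),
    sd_s = if (length(x) > 1) sd(x) else 0,
    n = length(x),
    histogram = hist_tbl
  )
}

#' Interval samples from replicate simulations, burn-in removed
#'
#' Convenience pipeline for fitting: detect bursts per trial, drop the
#' first `burn_in_bursts` bursts of each (initial-condition transients),
#' take first-to-first intervals, and pool across trials.
#'
#' @param series_list A list of [flash_series()] (see [run_replicates()]).
#' @param gap Burst gap threshold in seconds.
#' @param burn_in_bursts Bursts discarded at the start of each trial.
#' @return An `ibi_set` tibble of pooled intervals.
#' @export
pooled_burst_intervals <- function(series_list, gap = 2.0, burn_in_bursts = 5) {
  pooled <- purrr::map(series_list, function(fs) {
    train <- detect_bursts(fs, gap = gap)
    n_drop <- min(burn_in_bursts, max(nrow(train) - 2L, 0L))
    keep <- if (n_drop > 0) train$burst_start[-seq_len(n_drop)] else train$burst_start
    if (length(keep) < 2) return(numeric(0))
    diff(keep)
  })
  out <- tibble::tibble(interval_s = purrr::list_c(pooled))
  if (nrow(out) == 0) abort("No intervals left after burn-in.")
  structure(out,
    definition = "burst_first_to_first",
    class = c("ibi_set", class(out))
  )
}
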