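#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around [stats::ks.test()] (two-sided): D is the supremum
#' distance between the two empirical CDFs, the p-value uses the
#' asymptotic two-sample Kolmogorov distribution.
#'
#' @param a,b Interval samples: `ibi_set`/`ibi_samples` tibbles, data
#'   frames with `interval_s` or `ibi_s`, or numeric vectors.
#' @return A list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  x <- interval_values(a)
  y <- interval_values(b)
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  kt <- suppressWarnings(ks.test(x, y, alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

interval_values <- function(x) {
  if (is.data.frame(x)) {
    if ("interval_s" %in% names(x)) return(x$interval_s)
    if ("ibi_s" %in% names(x)) return(x$ibi_s)
    abort("Data frame input needs an `interval_s` or `ibi_s` column.")
  }
  as.numeric(x)
}

#' Sweep coupling strength and group size against reference intervals
#'
#' For every `(beta, N)` cell: run `n_trials` replicate simulations,
#' pool burn-in-trimmed first-to-first interburst intervals across
#' trials, and compare them with the reference interval sample for that
#' N via the two-sample KS statistic. The best-fit coupling per N
#' minimizes D.
#'
#' @param beta_grid Numeric vector of coupling strengths.
#' @param N_list Integer vector of group sizes.
#' @param reference A named list mapping each N (as character) to an
#'   interval sample (anything [ks_two_sample()] accepts), or a single
#'   sample used for every N.
#' @param config A [swarm_config()] used as a template; its `N` and
#'   `beta` are overridden cell by cell and its seed offsets per trial.
#' @param b Individual interburst-interval density.
#' @param d Flash-length density.
#' @param n_trials Replicates pooled per cell (default 10).
#' @param gap Burst gap threshold in seconds (default 2.0).
#' @return A list of class `beta_sweep` with elements `sweep` (tibble
#'   `N, beta, ks_D, ks_p`), `best` (tibble `N, best_beta, min_D`), and
#'   `n_trials`.
#' @export
beta_sweep <- function(beta_grid, N_list, reference, config, b, d,
                       n_trials = 10, gap = 2.0) {
  stopifnot(length(beta_grid) >= 1, length(N_list) >= 1)
  get_ref <- function(N) {
    if (is.data.frame(reference) || is.numeric(reference)) return(reference)
    key <- as.character(N)
    if (!key %in% names(reference)) {
      abort(sprintf("No reference sample provided for N = %d.", N))
    }
    reference[[key]]
  }
  cells <- tidyr::expand_grid(N = as.integer(N_list), beta = beta_grid)
  res <- purrr::pmap(cells, function(N, beta) {
    cfg <- config
    cfg$N <- N
    cfg$beta <- beta
    cfg$adjacency <- NULL
    sim <- tryCatch(
      {
        reps <- run_replicates(cfg, b, d, n_trials)
        pooled_burst_intervals(reps, gap = gap,
                               burn_in_bursts = cfg$burn_in_bursts)
      },
      error = function(e) {
        abort(sprintf("Sweep cell (beta = %.3g, N = %d) failed: %s",
                      beta, N, conditionMessage(e)))
      }
    )
    ks <- ks_two_sample(sim, get_ref(N))
    tibble::tibble(ks_D = ks$statistic, ks_p = ks$p_value)
  })
  sweep_tbl <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  out <- structure(
    list(sweep = sweep_tbl, n_trials = n_trials),
    class = "beta_sweep"
  )
  out$best <- select_best_beta(out)
  out
}

#' Best-fit coupling strength per group size
#'
#' Argmin of the KS statistic over the coupling grid, per N; ties break
#' toward the smaller coupling.
#'
#' @param result A `beta_sweep` (or its `sweep` tibble).
#' @return A tibble with columns `N`, `best_beta`, `min_D`.
#' @export
select_best_beta <- function(result) {
  tbl <- if (inherits(result, "beta_sweep")) result$sweep else result
  tbl |>
    dplyr::group_by(.data$N) |>
    dplyr::arrange(.data$ks_D, .data$beta, .by_group = TRUE) |>
    dplyr::summarise(
      best_beta = dplyr::first(.data$beta),
      min_D = dplyr::first(.data$ks_D)
    ) |>
    dplyr::ungroup()
}

#' @export
print.beta_sweep <- function(x, ...) {
  cat(sprintf(
    "<beta_sweep> %d cells (%d couplings x %d group sizes), %d pooled trials per cell\n",
    nrow(x$sweep), dplyr::n_distinct(x$sweep$beta),
    dplyr::n_distinct(x$sweep$N), x$n_trials
  ))
  print(x$best)
  invisible(x)
}

#' Tidy a coupling-strength sweep
#'
#' `tidy()` returns the full KS surface (one row per `(N, beta)` cell);
#' `glance()` returns the per-N best-fit summary.
#'
#' @param x A `beta_sweep` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy beta_sweep
#' @export
tidy.beta_sweep <- function(x, ...) x$sweep

#' @rdname tidy.beta_sweep
#' @method glance beta_sweep
#' @export
glance.beta_sweep <- function(x, ...) x$best
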