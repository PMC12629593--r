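#' Swarm simulation configuration
#'
#' Parameters of the stochastic pulse-coupled integrate-and-fire swarm.
#' Defaults follow the standard run protocol: 200000 Euler steps of
#' 0.009 s, i.e. 30 minutes of simulated time, all-to-all coupling with
#' per-pair strength `beta / N`.
#'
#' @param N Number of agents (`N >= 1`).
#' @param beta Coupling strength (dimensionless, `>= 0`); `beta = 0` is a
#'   fully non-interacting swarm, large `beta` approaches the
#'   instant-triggering idealization of [group_density()]. The swept
#'   range of interest is `[0, 1]`.
#' @param dt Timestep in seconds (default 0.009).
#' @param n_steps Number of timesteps (default 200000, so
#'   `n_steps * dt = 1800` s).
#' @param seed Integer RNG seed.
#' @param adjacency Optional binary symmetric N x N matrix with zero
#'   diagonal; `NULL` means all-to-all (every off-diagonal entry 1).
#' @param burn_in_bursts Number of initial collective bursts discarded
#'   before interval analysis (default 5), removing initial-condition
#'   transients.
#' @param gain Donation gain: the voltage pulse a visible flash onset
#'   donates is `gain * beta / N`. The default (4) calibrates the
#'   collective synchronization transition for a swarm of 20 under the
#'   default densities to just above `beta = 0.1`; see the methods
#'   vignette.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(N, beta, dt = 0.009, n_steps = 200000, seed = 1,
                         adjacency = NULL, burn_in_bursts = 5, gain = 4) {
  stopifnot(N >= 1, beta >= 0, dt > 0, n_steps >= 1, burn_in_bursts >= 0,
            gain > 0)
  if (!is.null(adjacency)) {
    adjacency <- as.matrix(adjacency)
    if (!all(dim(adjacency) == c(N, N))) abort("`adjacency` must be N x N.")
    if (!all(adjacency %in% c(0, 1))) abort("`adjacency` must be binary.")
    if (any(diag(adjacency) != 0)) abort("`adjacency` must have a zero diagonal.")
    if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
      abort("`adjacency` must be symmetric.")
    }
  }
  structure(
    list(
      N = as.integer(N), beta = beta, dt = dt,
      n_steps = as.integer(n_steps), seed = as.integer(seed),
      adjacency = adjacency, burn_in_bursts = as.integer(burn_in_bursts),
      gain = gain
    ),
    class = "swarm_config"
  )
}

#' @export
print.swarm_config <- function(x, ...) {
  cat(sprintf(
    "<swarm_config> N=%d beta=%.3g dt=%.4g s steps=%d (%.0f s) seed=%d %s\n",
    x$N, x$beta, x$dt, x$n_steps, x$n_steps * x$dt, x$seed,
    if (is.null(x$adjacency)) "all-to-all" else "custom adjacency"
  ))
  invisible(x)
}

# Strictly-increasing (cdf, grid) pair for inverse sampling: interior
# points of flat CDF stretches (zero-mass regions, e.g. the pad below
# t_min) are dropped and grid values clamped to the support, so the
# half-cell of trapezoid mass where the density ramps up from zero can
# never yield a draw below t_min.
reduced_cdf <- function(density) {
  cdf <- density_cdf_grid(density)
  inc <- diff(cdf) > 0
  keep <- c(FALSE, inc) | c(inc, FALSE)
  grid <- pmin(pmax(density$t_s[keep], t_min(density)), t_max(density))
  list(cdf = cdf[keep], grid = grid)
}

#' Construct a flash-series tibble
#'
#' @param agent_id Integer agent labels.
#' @param t_start,t_end Flash start/end times in seconds
#'   (`t_end > t_start`).
#' @param duration_s Total duration covered by the series, seconds.
#' @return A tibble of class `flash_series` sorted by `t_start`.
#' @export
flash_series <- function(agent_id, t_start, t_end, duration_s = NA_real_) {
  if (any(t_end <= t_start)) abort("Every flash needs t_end > t_start.")
  out <- tibble::tibble(
    agent_id = as.integer(agent_id),
    t_start = as.numeric(t_start),
    t_end = as.numeric(t_end)
  )
  out <- dplyr::arrange(out, .data$t_start, .data$agent_id)
  structure(out,
    duration_s = duration_s,
    class = c("flash_series", class(out))
  )
}

#' Run the stochastic integrate-and-fire swarm
#'
#' Each agent charges a voltage V at rate `1/Ts` while quiet, flashes when
#' V reaches 1, discharges at rate `1/Td` while flashing, and goes quiet
#' again at V = 0, at which point it resamples a fresh cycle: a
#' start-to-start interval Tb from `b` and a flash length Td from `d`
#' (rejected until Tb > Td), with charging time `Ts = Tb - Td`. Coupling
#' is pulsatile: the moment a neighbour starts flashing, every quiet
#' (charging) agent that sees it receives a voltage donation of
#' `gain * beta / N`, pulling its own flash earlier; flashing agents
#' ignore their neighbours, which is what ends a collective burst rather
#' than letting it re-trigger itself. Integration is forward Euler at
#' `dt` with V clamped to `[0, 1]` and synchronous state reads.
#'
#' @param config A [swarm_config()].
#' @param b Individual interburst-interval density ([ibi_density]).
#' @param d Flash-length density (see [flash_length_density()]).
#' @return A [flash_series()] of all completed flashes; identical
#'   `(config, b, d)` give bit-identical output.
#' @export
#' @examples
#' b <- parametric_density(ibi_model("shifted_exponential", t0 = 5, rate = 0.2))
#' cfg <- swarm_config(N = 5, beta = 0.2, n_steps = 20000, seed = 1)
#' flashes <- simulate_swarm(cfg, b, flash_length_density())
simulate_swarm <- function(config, b, d) {
  stopifnot(inherits(config, "swarm_config"))
  if (t_min(d) >= t_max(b)) {
    abort("Tb > Td unsatisfiable: the shortest flash length is not below the longest interburst interval.")
  }
  rb <- reduced_cdf(b)
  rd <- reduced_cdf(d)
  set.seed(config$seed)
  res <- .swarm_run(
    config$N, config$beta, config$gain, config$dt, config$n_steps,
    config$adjacency, rb$cdf, rb$grid, rd$cdf, rd$grid
  )
  if (length(res$agent_id) == 0) {
    abort("Simulation produced no completed flashes; increase n_steps.")
  }
  flash_series(res$agent_id, res$t_start, res$t_end,
    duration_s = config$n_steps * config$dt
  )
}

#' Replicate simulations with offset seeds
#'
#' Trial k runs with seed `config$seed + k - 1`, so replicates are
#' independent but the whole set is reproducible from the base seed.
#'
#' @inheritParams simulate_swarm
#' @param n_trials Number of replicate simulations.
#' @return A list of [flash_series()] objects, one per trial.
#' @export
run_replicates <- function(config, b, d, n_trials) {
  stopifnot(n_trials >= 1)
  purrr::map(seq_len(n_trials), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    simulate_swarm(cfg, b, d)
  })
}
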