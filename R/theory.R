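#' Survival function of an interval density
#'
#' gamma(t) = integral of b from t to infinity: the probability that an
#' isolated flasher waits longer than t before its next burst. Computed by
#' reverse cumulative trapezoid on the density grid, so gamma = 1 below the
#' refractory floor and 0 at the end of the support.
#'
#' @param density An [ibi_density].
#' @return A tibble of class `survival_curve` with columns `t_s`,
#'   `survival`, carrying the density's support attributes.
#' @export
survival_curve <- function(density) {
  gam <- 1 - density_cdf_grid(density)
  gam[density$t_s <= t_min(density)] <- 1
  gam[density$t_s >= t_max(density)] <- 0
  out <- tibble::tibble(t_s = density$t_s, survival = gam)
  structure(out,
    t_min = t_min(density), t_max = t_max(density),
    grid_step = grid_step(density),
    class = c("survival_curve", class(out))
  )
}

# gamma^k with log-space care for large exponents
surv_pow <- function(gam, k) {
  if (k == 0) return(rep(1, length(gam)))
  out <- numeric(length(gam))
  pos <- gam > 0
  out[pos] <- exp(k * log(gam[pos]))
  out
}

#' Group ("first to flash") interburst-interval density
#'
#' For N flashers each drawing waits independently from b(t), the interval
#' to the group's next burst is the minimum of N draws, with density
#' `P_N(t) = N * gamma(t)^(N-1) * b(t)`. The grid result is renormalized to
#' absorb discretization error.
#'
#' @param density An [ibi_density] for one individual.
#' @param N Number of flashers (`N >= 1`).
#' @return An [ibi_density] with an extra attribute `N`; for `N = 1` the
#'   input density (up to renormalization).
#' @export
#' @examples
#' b <- parametric_density(ibi_model("shifted_exponential", t0 = 5, rate = 0.2))
#' p20 <- group_density(b, 20)
group_density <- function(density, N) {
  stopifnot(N >= 1)
  gam <- survival_curve(density)$survival
  p <- N * surv_pow(gam, N - 1) * density$density
  out <- ibi_density(density$t_s, p,
    t_min = t_min(density), t_max = t_max(density),
    label = sprintf("group N=%d", N)
  )
  attr(out, "N") <- as.integer(N)
  out
}

#' Group density for heterogeneous individuals
#'
#' When each flasher i has its own density b_i, the first-to-flash density
#' is `sum_i b_i(t) * prod_{j != i} gamma_j(t)`. All densities must share
#' the same grid. With identical inputs this reduces exactly to
#' [group_density()].
#'
#' @param densities A list of [ibi_density] objects on a common grid.
#' @return An [ibi_density]; support runs from the smallest individual
#'   `t_min` (below which no one can flash) to the largest `t_max`.
#' @export
group_density_hetero <- function(densities) {
  stopifnot(length(densities) >= 1)
  grids <- purrr::map(densities, "t_s")
  if (!all(purrr::map_lgl(grids[-1], identical, grids[[1]]))) {
    abort("All densities must share an identical time grid.")
  }
  t_s <- grids[[1]]
  gams <- purrr::map(densities, ~ survival_curve(.x)$survival)
  p <- numeric(length(t_s))
  for (i in seq_along(densities)) {
    prod_others <- rep(1, length(t_s))
    for (j in seq_along(densities)) {
      if (j != i) prod_others <- prod_others * gams[[j]]
    }
    p <- p + densities[[i]]$density * prod_others
  }
  out <- ibi_density(t_s, p,
    t_min = min(purrr::map_dbl(densities, t_min)),
    t_max = max(purrr::map_dbl(densities, t_max)),
    label = sprintf("group (heterogeneous, N=%d)", length(densities))
  )
  attr(out, "N") <- length(densities)
  out
}

#' Moments of the group interburst interval
#'
#' Uses the survival-function identity
#' `<T_N^m> = m * integral( gamma(t)^N * t^(m-1) dt )` (for `m >= 1`),
#' which is numerically stable for very large N: below the refractory floor
#' gamma = 1 and the integrand is exact.
#'
#' @param density An [ibi_density] for one individual.
#' @param N Group size.
#' @param m Moment order (`m >= 0`; `m = 0` returns 1).
#' @return A number in seconds^m.
#' @export
group_moment <- function(density, N, m = 1) {
  stopifnot(N >= 1, m >= 0)
  if (m == 0) return(1)
  gam_n <- surv_pow(survival_curve(density)$survival, N)
  m * trapz(density$t_s, gam_n * density$t_s^(m - 1))
}

#' @rdname group_moment
#' @export
group_mean <- function(density, N) group_moment(density, N, 1)

#' Variance of the group interburst interval
#'
#' `V_N = <T^2> - <T>^2`, both moments via [group_moment()]. Monotonically
#' non-increasing in N for any individual density.
#'
#' @inheritParams group_moment
#' @return A number in seconds^2 (non-negative up to quadrature noise).
#' @export
group_variance <- function(density, N) {
  group_moment(density, N, 2) - group_moment(density, N, 1)^2
}

#' Standard deviation of the group interval across group sizes
#'
#' The sharpening of the collective rhythm: the spread of the group
#' interburst interval shrinks as the group grows.
#'
#' @param density An [ibi_density] for one individual.
#' @param Ns Integer vector of group sizes.
#' @return A tibble with columns `N` and `sd_s` (seconds), `sd_s`
#'   non-increasing in `N`.
#' @export
std_vs_N <- function(density, Ns) {
  stopifnot(length(Ns) >= 1)
  tibble::tibble(
    N = as.integer(Ns),
    sd_s = purrr::map_dbl(Ns, ~ sqrt(max(group_variance(density, .x), 0)))
  )
}

#' Left-most mode of a gridded density
#'
#' The earliest local maximum on the grid: the first grid point in the
#' support whose density exceeds its left neighbour and is at least its
#' right neighbour (ties resolve toward smaller t; a maximum sitting at
#' the support edge `t_min` counts). For group densities the left-most
#' mode moves left as N grows, with floor `t_min`.
#'
#' @param density An [ibi_density] (for example from [group_density()]).
#' @return Time of the mode in seconds.
#' @export
leftmost_mode <- function(density) {
  d <- density$density
  if (all(d == 0)) abort("Flat zero density has no mode.")
  left <- c(0, d[-length(d)])
  right <- c(d[-1], 0)
  is_mode <- d > 0 & d > left & d >= right
  idx <- which(is_mode)
  if (length(idx) == 0) idx <- which.max(d)
  density$t_s[idx[1]]
}

#' Monte-Carlo oracle: empirical minimum of N draws
#'
#' Brute-force check of the group density: draw N intervals from b and
#' keep the minimum, `n_samples` times. The empirical distribution should
#' match the analytic group density.
#'
#' @param density An [ibi_density].
#' @param N Group size.
#' @param n_samples Number of minima to generate.
#' @param seed Optional integer seed.
#' @return An `ibi_samples` tibble of `n_samples` minima.
#' @export
min_of_n_oracle <- function(density, N, n_samples, seed = NULL) {
  stopifnot(N >= 1, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(sample_ibi(density, n_samples * N), ncol = N)
  mins <- do.call(pmin, as.data.frame(draws))
  out <- tibble::tibble(ibi_s = mins)
  structure(out,
    n_removed = 0L, cutoff = 0,
    label = sprintf("min-of-%d oracle", N),
    class = c("ibi_samples", class(out))
  )
}
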