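#' Gridded interburst-interval densities
#'
#' An `ibi_density` is a waiting-time probability density b(t) tabulated on a
#' uniform time grid starting at 0. It has hard support `[t_min, t_max]`:
#' the density is exactly zero below the refractory floor `t_min` (the
#' shortest physiologically possible interval) and above `t_max`. Between
#' grid points the density is treated as piecewise linear, so all integrals
#' are trapezoidal and the total area is 1.
#'
#' @param t_s Numeric vector, uniform time grid in seconds starting at 0.
#' @param density Non-negative density values, one per grid point.
#' @param t_min,t_max Support bounds in seconds (`0 <= t_min < t_max`).
#' @param renormalize Rescale so the trapezoid integral is exactly 1.
#' @param label Free-text provenance tag.
#'
#' @return A tibble of class `ibi_density` with columns `t_s` and `density`
#'   and attributes `t_min`, `t_max`, `grid_step`, `label`.
#' @export
ibi_density <- function(t_s, density, t_min, t_max,
                        renormalize = TRUE, label = NULL) {
  stopifnot(length(t_s) == length(density), length(t_s) >= 2)
  steps <- diff(t_s)
  grid_step <- steps[1]
  if (any(abs(steps - grid_step) > 1e-8 * grid_step)) {
    abort("`t_s` must be a uniform grid.")
  }
  if (t_s[1] != 0) abort("The grid must start at 0.")
  if (!(t_min >= 0 && t_min < t_max)) abort("Need 0 <= t_min < t_max.")
  density[t_s < t_min | t_s > t_max] <- 0
  density[density < 0] <- 0
  area <- trapz(t_s, density)
  if (area <= 0) abort("Density is identically zero on its support.")
  if (renormalize) density <- density / area
  out <- tibble::tibble(t_s = t_s, density = density)
  structure(out,
    t_min = t_min, t_max = t_max, grid_step = grid_step,
    label = label %||% "ibi_density",
    class = c("ibi_density", class(out))
  )
}

#' @export
print.ibi_density <- function(x, ...) {
  cat(sprintf(
    "<ibi_density> %s\n  support [%.3f, %.3f] s, grid step %.4g s, %d points\n",
    attr(x, "label"), attr(x, "t_min"), attr(x, "t_max"),
    attr(x, "grid_step"), nrow(x)
  ))
  cat(sprintf(
    "  mean %.3f s, sd %.3f s\n",
    density_moment(x, 1), sqrt(density_variance(x))
  ))
  invisible(x)
}

# trapezoid rule on an arbitrary grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Support and grid accessors
#'
#' @param density An [ibi_density].
#' @return A number (seconds).
#' @export
t_min <- function(density) attr(density, "t_min")

#' @rdname t_min
#' @export
t_max <- function(density) attr(density, "t_max")

#' @rdname t_min
#' @export
grid_step <- function(density) attr(density, "grid_step")

#' Raw moments and variance of a gridded density
#'
#' Trapezoid quadrature of `t^m b(t)` over the grid.
#'
#' @param density An [ibi_density].
#' @param m Moment order (non-negative integer).
#' @return A number in seconds^m (`density_moment`) or seconds^2
#'   (`density_variance`).
#' @export
density_moment <- function(density, m = 1) {
  if (m == 0) return(1)
  trapz(density$t_s, density$t_s^m * density$density)
}

#' @rdname density_moment
#' @export
density_variance <- function(density) {
  density_moment(density, 2) - density_moment(density, 1)^2
}

#' Piecewise-linear cumulative distribution of a gridded density
#'
#' Returns the CDF evaluated at the grid points (cumulative trapezoid), or a
#' vectorized closure suitable for one-sample Kolmogorov-Smirnov tests.
#' The CDF is conditioned on the hard support: the sliver of trapezoid
#' mass accrued where the piecewise-linear density ramps up across
#' `t_min` is a grid artifact and is removed, so the CDF is exactly 0 at
#' (and below) the refractory floor. This keeps inverse-CDF sampling and
#' analytic survival curves mutually consistent.
#'
#' @param density An [ibi_density].
#' @return `density_cdf_grid()`: a numeric vector aligned with the grid,
#'   starting at 0 and ending at 1. `density_cdf()`: a function of time.
#' @export
density_cdf_grid <- function(density) {
  y <- density$density
  n <- length(y)
  cdf <- c(0, cumsum((y[-1] + y[-n]) * diff(density$t_s)) / 2)
  c0 <- max(cdf[density$t_s <= attr(density, "t_min")], 0)
  pmax(cdf - c0, 0) / (cdf[n] - c0)
}

#' @rdname density_cdf_grid
#' @export
density_cdf <- function(density) {
  grid <- density$t_s
  cdf <- density_cdf_grid(density)
  function(q) {
    stats::approx(grid, cdf, xout = q, yleft = 0, yright = 1, ties = "ordered")$y
  }
}

#' Parametric interburst-interval models
#'
#' Small parametric families used as synthetic stand-ins for the broad,
#' heavy-right-tailed waiting-time distributions of isolated flashers: a
#' hard refractory floor `t0` plus either an exponential or a lognormal
#' excess. Both are truncated at `t_max` and renormalized when gridded.
#'
#' @param family `"shifted_exponential"` or `"shifted_lognormal"`.
#' @param t0 Refractory floor in seconds (shift; `t0 >= 0`).
#' @param rate Exponential rate in 1/s (shifted exponential only).
#' @param meanlog,sdlog Lognormal parameters of the excess `t - t0`
#'   (shifted lognormal only). `exp(meanlog)` is the median excess.
#' @param t_max Truncation point in seconds; defaults to the 1 - 1e-8
#'   quantile so truncation is numerically immaterial.
#' @return An object of class `ibi_model`.
#' @export
#' @examples
#' m <- ibi_model("shifted_exponential", t0 = 5, rate = 0.2)
#' b <- parametric_density(m, grid_step = 0.1)
ibi_model <- function(family = c("shifted_exponential", "shifted_lognormal"),
                      t0, rate = NULL, meanlog = NULL, sdlog = NULL,
                      t_max = NULL) {
  family <- match.arg(family)
  stopifnot(is.finite(t0), t0 >= 0)
  if (family == "shifted_exponential") {
    stopifnot(is.finite(rate), rate > 0)
    t_max <- t_max %||% (t0 + qexp(1 - 1e-8) / rate)
  } else {
    stopifnot(is.finite(meanlog), is.finite(sdlog), sdlog > 0)
    t_max <- t_max %||% (t0 + qlnorm(1 - 1e-8, meanlog, sdlog))
  }
  if (t_max <= t0) abort("`t_max` must exceed `t0`.")
  structure(
    list(family = family, t0 = t0, rate = rate,
         meanlog = meanlog, sdlog = sdlog, t_max = t_max),
    class = "ibi_model"
  )
}

#' Grid a parametric interburst-interval model
#'
#' @param model An [ibi_model].
#' @param grid_step Grid resolution in seconds.
#' @return An [ibi_density] on `[0, t_max]`, renormalized after truncation.
#' @export
parametric_density <- function(model, grid_step = 0.1) {
  stopifnot(inherits(model, "ibi_model"), grid_step > 0)
  t_s <- seq(0, ceiling(model$t_max / grid_step) * grid_step, by = grid_step)
  x <- t_s - model$t0
  dens <- if (model$family == "shifted_exponential") {
    ifelse(x >= 0, model$rate * exp(-model$rate * pmax(x, 0)), 0)
  } else {
    ifelse(x > 0, dlnorm(pmax(x, 1e-300), model$meanlog, model$sdlog), 0)
  }
  ibi_density(t_s, dens,
    t_min = model$t0, t_max = model$t_max,
    label = model$family
  )
}

#' Draw parametric samples directly from an `ibi_model`
#'
#' Exact (non-gridded) draws from the parametric family, truncated at
#' `t_max` by rejection. Used to fabricate realistic raw interval tables.
#'
#' @param model An [ibi_model].
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of intervals in seconds.
#' @export
sample_model <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(k) {
    if (model$family == "shifted_exponential") {
      model$t0 + stats::rexp(k, model$rate)
    } else {
      model$t0 + stats::rlnorm(k, model$meanlog, model$sdlog)
    }
  }
  out <- draw(n)
  while (any(bad <- out > model$t_max)) out[bad] <- draw(sum(bad))
  out
}

#' Default flash-length (discharge duration) density
#'
#' Flash discharges last on the order of a second; this shifted-lognormal
#' default (floor 0.2 s, median 1.0 s, sigma 0.3) is a configurable
#' synthetic stand-in for observed flash-length distributions.
#'
#' @param t0 Minimum discharge duration in seconds (must be > 0).
#' @param median Median discharge duration in seconds.
#' @param sigma Lognormal shape of the excess over `t0`.
#' @param grid_step Grid resolution in seconds (finer than the interval
#'   grid because flashes are short).
#' @return An [ibi_density] usable as a flash-length density.
#' @export
flash_length_density <- function(t0 = 0.2, median = 1.0, sigma = 0.3,
                                 grid_step = 0.01) {
  stopifnot(t0 > 0, median > t0)
  m <- ibi_model("shifted_lognormal",
    t0 = t0, meanlog = log(median - t0), sdlog = sigma
  )
  d <- parametric_density(m, grid_step = grid_step)
  attr(d, "label") <- "flash_length"
  d
}
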