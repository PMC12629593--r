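# Shared density fixtures, built in code. Fine grids (0.01 s) keep
# quadrature error well below the tolerances the tests assert.

exp_density <- function(t0 = 5, rate = 0.2, grid_step = 0.01) {
  parametric_density(ibi_model("shifted_exponential", t0 = t0, rate = rate),
                     grid_step = grid_step)
}

lnorm_density <- function(t0 = 5.672, median = 30, sigma = 1, grid_step = 0.1) {
  parametric_density(
    ibi_model("shifted_lognormal", t0 = t0, meanlog = log(median), sdlog = sigma),
    grid_step = grid_step
  )
}

# bimodal interval density with a hard floor at 8 s
mixture_density <- function(grid_step = 0.01) {
  t_s <- seq(0, 60, by = grid_step)
  dens <- dnorm(t_s, 15, 2) + 0.6 * dnorm(t_s, 30, 4)
  ibi_density(t_s, dens, t_min = 8, t_max = 60, label = "bimodal mixture")
}

# uniform density on [1, 2]
uniform_density <- function(grid_step = 0.001) {
  t_s <- seq(0, 2, by = grid_step)
  dens <- as.numeric(t_s >= 1 & t_s <= 2)
  ibi_density(t_s, dens, t_min = 1, t_max = 2, label = "uniform [1,2]")
}

# near-delta density: all mass in one narrow cell around `at`
spike_density <- function(at = 10, width = 0.1, grid_step = 0.01) {
  t_s <- seq(0, at + 1, by = grid_step)
  dens <- as.numeric(abs(t_s - at) <= width / 2)
  ibi_density(t_s, dens, t_min = at - width / 2, t_max = at + width / 2,
              label = "spike")
}
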