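test_that("survival curve is a proper complementary CDF", {
  b <- exp_density(t0 = 5, rate = 0.2)
  g <- survival_curve(b)
  expect_equal(g$survival[1], 1, tolerance = 1e-6)
  expect_equal(g$survival[g$t_s == 10], exp(-1), tolerance = 0.01)
  expect_equal(g$survival[nrow(g)], 0, tolerance = 1e-6)
  expect_true(all(diff(g$survival) <= 1e-12))
})

test_that("group density reduces to b at N = 1 and matches the min-of-N closed form", {
  b <- exp_density(t0 = 5, rate = 0.2)
  p1 <- group_density(b, 1)
  expect_equal(p1$density, b$density, tolerance = 1e-6)

  # min of N shifted exponentials is shifted exponential with rate N*lambda
  p10 <- group_density(b, 10)
  expect_equal(density_moment(p10, 1), 5.5, tolerance = 0.005)

  u <- uniform_density()
  p2u <- group_density(u, 2)
  expect_equal(density_moment(p2u, 1), 4 / 3, tolerance = 0.005)

  expect_error(group_density(b, 0))
})

test_that("heterogeneous group density reduces correctly", {
  b <- exp_density(t0 = 5, rate = 0.2, grid_step = 0.01)
  hom <- group_density(b, 3)
  het <- group_density_hetero(list(b, b, b))
  expect_equal(het$density, hom$density, tolerance = 1e-9)

  b1 <- exp_density(t0 = 5, rate = 0.1, grid_step = 0.01)
  b3 <- exp_density(t0 = 5, rate = 0.3, grid_step = 0.01)
  # min of independent exponentials: rates add
  common <- seq(0, max(t_max(b1), t_max(b3)), by = 0.01)
  regrid <- function(bb) {
    dens <- approx(bb$t_s, bb$density, xout = common, yleft = 0, yright = 0)$y
    ibi_density(common, dens, t_min = t_min(bb), t_max = t_max(bb))
  }
  pair <- group_density_hetero(list(regrid(b1), regrid(b3)))
  expect_equal(density_moment(pair, 1), 5 + 1 / 0.4, tolerance = 0.005)

  single <- group_density_hetero(list(b))
  expect_equal(single$density, b$density, tolerance = 1e-9)

  expect_error(group_density_hetero(list(b1, exp_density(grid_step = 0.02))),
               "identical time grid")
})

test_that("moments follow the survival-function identity and decrease strictly in N", {
  b <- exp_density(t0 = 5, rate = 0.2)
  expect_identical(group_moment(b, 5, 0), 1)
  expect_equal(group_moment(b, 10, 1), 5.5, tolerance = 0.005)

  for (m in 1:3) {
    vals <- sapply(c(1, 2, 5, 10, 20, 50), function(N) group_moment(b, N, m))
    expect_true(all(diff(vals) < -1e-9),
                label = sprintf("moment order %d strictly decreasing", m))
  }

  mix <- mixture_density()
  for (m in 1:3) {
    vals <- sapply(1:30, function(N) group_moment(mix, N, m))
    expect_true(all(diff(vals) < -1e-9))
  }
})

test_that("variance matches the closed form and never increases with N", {
  b <- exp_density(t0 = 5, rate = 0.2)
  expect_equal(group_variance(b, 10), 1 / (10 * 0.2)^2, tolerance = 0.01)

  for (dens in list(b, mixture_density())) {
    v <- sapply(1:200, function(N) group_variance(dens, N))
    expect_true(all(diff(v) <= 1e-9))
    expect_true(all(v >= -1e-9))
  }

  spike <- spike_density()
  expect_lt(group_variance(spike, 1), 0.01)
  expect_lt(group_variance(spike, 50), 0.01)
})

test_that("group standard deviation shrinks as 1/(N*lambda) for shifted exponentials", {
  b <- exp_density(t0 = 5, rate = 0.2)
  tbl <- std_vs_N(b, c(1, 2, 5, 10, 20, 50))
  expect_equal(tbl$sd_s, 1 / (tbl$N * 0.2), tolerance = 0.01)
  expect_true(all(diff(tbl$sd_s) < 0))

  one <- std_vs_N(b, 1)
  expect_equal(one$sd_s, sqrt(density_variance(b)), tolerance = 1e-3)

  mix_tbl <- std_vs_N(mixture_density(), 1:100)
  expect_true(all(diff(mix_tbl$sd_s) < 0))
})

test_that("left-most mode sits at the floor for decreasing densities and drifts left otherwise", {
  b <- exp_density(t0 = 5, rate = 0.2)
  expect_equal(leftmost_mode(group_density(b, 7)), t_min(b))

  mix <- mixture_density()
  modes <- sapply(c(1, 2, 5, 10, 20, 50, 100), function(N) {
    leftmost_mode(group_density(mix, N))
  })
  expect_true(all(diff(modes) <= 1e-9))
  expect_true(all(modes >= t_min(mix)))

  big <- leftmost_mode(group_density(mix, 1e4))
  expect_lte(big, t_min(mix) + grid_step(mix))
})

test_that("the group distribution concentrates at the refractory floor for huge N", {
  for (dens in list(exp_density(), {
    set.seed(13)
    build_envelope(sample_model(
      ibi_model("shifted_exponential", t0 = 6, rate = 0.05), 5000
    ))
  })) {
    mean_big <- group_moment(dens, 1e4, 1)
    expect_lt(abs(mean_big - t_min(dens)), 2 * grid_step(dens))
    v <- group_variance(dens, 1e4)
    expect_lt(sqrt(max(v, 0)), 0.01 * (t_max(dens) - t_min(dens)))
  }
})

test_that("Monte-Carlo minima agree with the analytic group density", {
  shapes <- list(exp_density(), lnorm_density(grid_step = 0.01), mixture_density())
  for (b in shapes) {
    for (N in c(2, 5, 20)) {
      mins <- min_of_n_oracle(b, N, 1e5, seed = 100 + N)
      expect_true(all(mins$ibi_s >= t_min(b)))
      D <- suppressWarnings(
        ks.test(mins$ibi_s, density_cdf(group_density(b, N)))
      )$statistic
      expect_lt(D, 0.01)
    }
  }
})

test_that("min-of-1 oracle is plain sampling", {
  b <- exp_density()
  a <- min_of_n_oracle(b, 1, 1000, seed = 9)
  expect_identical(a$ibi_s, sample_ibi(b, 1000, seed = 9))
})
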