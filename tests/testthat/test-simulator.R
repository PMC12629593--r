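test_that("default protocol covers 30 minutes of simulated time", {
  cfg <- swarm_config(N = 20, beta = 0.3)
  expect_equal(cfg$n_steps * cfg$dt, 1800)
})

test_that("simulation is bit-identical for identical seeds and differs across trials", {
  b <- exp_density()
  d <- flash_length_density()
  cfg <- swarm_config(N = 5, beta = 0.2, n_steps = 30000, seed = 42)
  f1 <- simulate_swarm(cfg, b, d)
  f2 <- simulate_swarm(cfg, b, d)
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  reps <- run_replicates(cfg, b, d, 2)
  expect_false(identical(as.data.frame(reps[[1]]), as.data.frame(reps[[2]])))
  # trial 1 reuses the base seed
  expect_identical(as.data.frame(reps[[1]]), as.data.frame(f1))
})

test_that("flash records are well-formed per agent", {
  b <- exp_density()
  d <- flash_length_density()
  fs <- simulate_swarm(swarm_config(N = 10, beta = 0.3, n_steps = 50000, seed = 8), b, d)
  expect_true(all(fs$t_end > fs$t_start))
  by_agent <- split(fs, fs$agent_id)
  for (records in by_agent) {
    expect_true(all(diff(records$t_start) > 0))
    # no overlap: each flash ends before the next begins
    expect_true(all(utils::head(records$t_end, -1) <= records$t_start[-1]))
  }
})

test_that("a lone uncoupled agent renews at its sampled interval", {
  # near-delta densities: interval ~ 10 s, flash ~ 1 s
  b <- spike_density(at = 10, width = 0.1)
  d <- spike_density(at = 1, width = 0.02)
  cfg <- swarm_config(N = 1, beta = 0, n_steps = 50000, seed = 3)
  fs <- simulate_swarm(cfg, b, d)
  gaps <- diff(fs$t_start)
  expect_true(all(abs(gaps - 10) <= 0.1 + 2 * cfg$dt))
  # flash lengths track the discharge density
  expect_true(all(abs((fs$t_end - fs$t_start) - 1) <= 0.02 + 2 * cfg$dt))
})

test_that("a lone uncoupled agent reproduces the input interval distribution", {
  b <- exp_density()
  d <- flash_length_density()
  cfg <- swarm_config(N = 1, beta = 0, n_steps = 200000, seed = 21)
  iv <- pooled_burst_intervals(run_replicates(cfg, b, d, 5))
  expect_gt(nrow(iv), 150)
  D <- suppressWarnings(ks.test(iv$interval_s, density_cdf(b)))$statistic
  expect_lt(D, 0.05)
})

test_that("uncoupled swarms superpose independently", {
  b <- exp_density()
  d <- flash_length_density()
  one <- simulate_swarm(swarm_config(N = 1, beta = 0, n_steps = 100000, seed = 5), b, d)
  many <- simulate_swarm(swarm_config(N = 20, beta = 0, n_steps = 100000, seed = 5), b, d)
  # pooled flash count scales like N for non-interacting agents
  expect_equal(nrow(many) / nrow(one), 20, tolerance = 0.2)
  # and pooled flash-to-flash intervals pile up below the individual floor
  mode_s <- summarize_intervals(flash_to_flash_intervals(many), 0.5)$mode_s
  expect_lt(mode_s, t_min(b))
})

test_that("strong coupling drives the group interval toward the analytic extreme-value law", {
  b <- exp_density()
  d <- flash_length_density()
  cfg <- swarm_config(N = 20, beta = 5, n_steps = 200000, seed = 11)
  iv <- pooled_burst_intervals(run_replicates(cfg, b, d, 5))
  p20 <- group_density(b, 20)
  D <- suppressWarnings(ks.test(iv$interval_s, density_cdf(p20)))$statistic
  expect_lt(D, 0.1)
  expect_equal(mean(iv$interval_s), group_mean(b, 20), tolerance = 0.02)
})

test_that("unsatisfiable flash lengths are rejected at startup", {
  b <- spike_density(at = 3, width = 0.1)     # intervals near 3 s
  d <- spike_density(at = 5, width = 0.1)     # flashes near 5 s: impossible
  cfg <- swarm_config(N = 2, beta = 0, n_steps = 1000, seed = 1)
  expect_error(simulate_swarm(cfg, b, d), "unsatisfiable")
})

test_that("adjacency must be binary, symmetric, zero-diagonal", {
  expect_error(swarm_config(N = 3, beta = 0.1, adjacency = matrix(1, 3, 3)),
               "zero diagonal")
  adj <- matrix(0, 3, 3); adj[1, 2] <- 1
  expect_error(swarm_config(N = 3, beta = 0.1, adjacency = adj), "symmetric")
  expect_error(swarm_config(N = 2, beta = 0.1, adjacency = matrix(0, 3, 3)),
               "N x N")
  adj <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_s3_class(swarm_config(N = 2, beta = 0.1, adjacency = adj), "swarm_config")
})

test_that("an isolated pair via adjacency matches an uncoupled pair", {
  b <- exp_density()
  d <- flash_length_density()
  adj <- matrix(0, 2, 2)
  cfg_discon <- swarm_config(N = 2, beta = 5, n_steps = 30000, seed = 6, adjacency = adj)
  cfg_beta0 <- swarm_config(N = 2, beta = 0, n_steps = 30000, seed = 6)
  expect_identical(
    as.data.frame(simulate_swarm(cfg_discon, b, d)),
    as.data.frame(simulate_swarm(cfg_beta0, b, d))
  )
})
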