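test_that("ground-truth simulation conserves moieties in batch mode", {
  scen <- toy_pulse_scenario(seed = 1)
  tr <- simulate_ground_truth(scen)
  W <- conserved_moieties(scen$generating_network)
  q <- tr$states %*% W
  q0 <- drop(scen$y0 %*% W)
  for (j in seq_len(ncol(W)))
    expect_lt(max(abs(q[, j] - q0[j])), 1e-6 * max(abs(q0[j]), 1e-3))
})

test_that("zero initial state with no inflow stays identically zero", {
  net <- toy_oscillator()$network
  scen <- scenario(net, mode = "batch", y0 = rep(0, 7),
                   measurement_times = seq(0, 2, by = 0.5),
                   measured = c(1, 2, 6, 7))
  tr <- simulate_ground_truth(scen)
  expect_true(all(tr$states == 0))
})

test_that("make_measurements reduces to the truth at zero noise", {
  scen <- toy_pulse_scenario(seed = 3)
  tr <- simulate_ground_truth(scen)
  ms <- make_measurements(tr, noise_sd = 0, replicates = 2,
                          times = scen$measurement_times,
                          measured = scen$measured, seed = 1)
  truth_at <- sapply(seq_len(7), function(k)
    approx(tr$times, tr$states[, k], xout = ms$times)$y)
  expect_equal(ms$mean, truth_at, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(ms$std == 0))
})

test_that("two replicates give std = |r1 - r2| / sqrt(2)", {
  # with two draws the sample standard deviation (n - 1 denominator)
  # equals |r1 - r2| / sqrt(2); reconstruct the draws from mean and std
  tr <- trajectory(0:5, matrix(rep(0.5, 6), 6, 1), species = "A")
  ms <- make_measurements(tr, noise_sd = 0.05, replicates = 2, seed = 7,
                          measured = 1)
  r1 <- ms$mean[, 1] + ms$std[, 1] / sqrt(2)
  r2 <- ms$mean[, 1] - ms$std[, 1] / sqrt(2)
  expect_equal(sqrt((r1 - r2)^2 / 2), ms$std[, 1], tolerance = 1e-12)
  expect_equal(apply(cbind(r1, r2), 1, sd), ms$std[, 1], tolerance = 1e-10)
})

test_that("pooled replicate std concentrates on the true noise level", {
  # chi-distribution concentration: at 10 000 replicates the pooled std is
  # within a fraction of a percent of the generating sd
  tr <- trajectory(c(0, 1), matrix(c(1, 1), 2, 1), species = "A")
  ms <- make_measurements(tr, noise_sd = 0.01, replicates = 10000, seed = 11,
                          measured = 1)
  expect_lt(abs(ms$std[1, 1] - 0.01) / 0.01, 0.05)
  expect_lt(abs(ms$mean[1, 1] - 1), 4 * 0.01 / sqrt(10000))
})

test_that("sampling statistics match the declared normal model", {
  times <- 0:3
  mean <- matrix(c(1, 2, 3, 4, 0.5, 0.5, 0.5, 0.5), 4, 2)
  std <- matrix(c(0.1, 0.1, 0.1, 0.1, 0.02, 0.02, 0.02, 0.02), 4, 2)
  ms <- measurement_series(times, mean, std, measured = 1:2)
  n <- 10000
  ds <- sample_dataset(ms, n, seed = 5)
  # per-cell sample mean within 4 std / sqrt(n) of the declared mean
  for (tkn in 1:4) for (k in 1:2) {
    expect_lt(abs(mean(ds$samples[, tkn, k]) - mean[tkn, k]),
              4 * std[tkn, k] / sqrt(n))
    expect_lt(abs(sd(ds$samples[, tkn, k]) - std[tkn, k]) / std[tkn, k], 0.05)
  }
  # degenerate normal: zero std reproduces the mean series exactly
  ms0 <- measurement_series(times, mean, std * 0, measured = 1:2)
  ds0 <- sample_dataset(ms0, 5, seed = 1)
  for (i in 1:5)
    expect_equal(matrix(ds0$samples[i, , ], 4, 2), mean, ignore_attr = TRUE)
  # determinism and seed sensitivity
  expect_identical(sample_dataset(ms, 3, seed = 9)$samples,
                   sample_dataset(ms, 3, seed = 9)$samples)
  expect_false(identical(sample_dataset(ms, 3, seed = 9)$samples,
                         sample_dataset(ms, 3, seed = 10)$samples))
  # negative draws are clipped at zero
  ms_neg <- measurement_series(0:1, matrix(0.001, 2, 1), matrix(1, 2, 1),
                               measured = 1)
  ds_neg <- sample_dataset(ms_neg, 500, seed = 2)
  expect_true(all(ds_neg$samples >= 0))
})

test_that("hidden_interaction_scenario wires the ablation through", {
  scen0 <- toy_pulse_scenario(seed = 2)
  scen <- hidden_interaction_scenario(scen0, "slow_inhibition", species = 7)
  expect_identical(scen$generating_network, scen0$generating_network)
  rhs_g <- build_rhs(scen$generating_network)
  rhs_m <- build_rhs(scen$modeling_network)
  k2 <- scen$generating_network$kappa["k_inh2"]
  set.seed(8)
  for (i in 1:20) {
    y <- random_nonneg_state(7)
    diff7 <- rhs_g(0, y)[7] - rhs_m(0, y)[7]
    expect_equal(diff7, unname(k2 * y[1] * y[4]), tolerance = 1e-12)
  }
  # the null scenario leaves the model identical
  expect_identical(hidden_interaction_scenario(scen0, NULL), scen0)
})

test_that("ablated theory fit is strictly worse than the null scenario's", {
  scen <- hidden_interaction_scenario(toy_pulse_scenario(seed = 4),
                                      "slow_inhibition", species = 7)
  dat <- generate_scenario_data(scen)
  ds <- sample_dataset(dat$measurements, 16, seed = 4)
  cfg <- solver_config("esdirk3", rtol = 1e-6, atol = 1e-9)
  mse_full <- crnode:::predict_dataset_mse(scen$generating_network, ds,
                                           config = cfg)
  mse_abl <- crnode:::predict_dataset_mse(scen$modeling_network, ds,
                                          config = cfg)
  expect_gt(mse_abl, mse_full)
})

test_that("measurement series round-trips through CSV bit-identically", {
  scen <- toy_pulse_scenario(seed = 6)
  ms <- generate_scenario_data(scen)$measurements
  path <- tempfile(fileext = ".csv")
  write_measurements(ms, path)
  back <- read_measurements(path)
  expect_identical(back$times, ms$times)
  expect_identical(unname(back$mean), unname(ms$mean))
  expect_identical(unname(back$std), unname(ms$std))
  expect_identical(back$measured, ms$measured)
  expect_identical(back$time_unit, ms$time_unit)
})
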