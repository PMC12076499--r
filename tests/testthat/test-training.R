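test_that("mse_loss is the masked mean squared error", {
  Tn <- 6; M <- 4
  pred <- matrix(rnorm(Tn * M), Tn, M)
  obs <- pred
  expect_identical(mse_loss(pred, obs, measured = 1:3), 0)
  # constant offset delta on one masked-in species among K masked species
  delta <- 0.3
  obs2 <- pred; obs2[, 2] <- obs2[, 2] + delta
  expect_equal(mse_loss(pred, obs2, measured = c(1, 2, 4)), delta^2 / 3)
  # offset on a masked-out species contributes nothing
  obs3 <- pred; obs3[, 4] <- obs3[, 4] + 100
  expect_identical(mse_loss(pred, obs3, measured = 1:3), 0)
  expect_error(mse_loss(pred[1:3, ], obs, 1:2), "mismatch")
})

test_that("adabelief matches the reference update on a hand-computed step", {
  # one step from zero state: m = (1-b1) g, s = (1-b2)(g - m)^2 + eps,
  # bias-corrected, update = lr * mhat / (sqrt(shat) + eps)
  g <- c(1, -2, 0.5)
  lr <- 0.01; b1 <- 0.9; b2 <- 0.999; eps <- 1e-16
  st <- crnode:::adabelief_step(c(0, 0, 0), g, NULL, lr, b1, b2, eps)
  m <- (1 - b1) * g
  s <- (1 - b2) * (g - m)^2 + eps
  expected <- -lr * (m / (1 - b1)) / (sqrt(s / (1 - b2)) + eps)
  expect_equal(st$theta, expected, tolerance = 1e-12)
})

test_that("dropout is rejected by the training configuration", {
  expect_error(training_config(dropout = 0.1), "dropout")
  expect_error(training_config(curriculum = 0), "curriculum")
})

test_that("training on well-specified noiseless data stays at the theory", {
  # data generated exactly by h_kappa: the zero-initialized correction is
  # already optimal, the best checkpoint must stay essentially there
  scen <- toy_pulse_scenario(seed = 5, n_times = 9)
  scen$noise_sd[] <- 0
  dat <- generate_scenario_data(scen)
  ms <- dat$measurements
  corr <- init_correction(4, 32, seed = 5, measured = scen$measured)
  cfg <- training_config(n_train = 8, n_val = 4, steps_per_phase = 3,
                         batch_size = 8, seed = 5, val_every = 3,
                         solver = solver_config("dopri5", rtol = 1e-6,
                                                atol = 1e-9))
  fit <- train(scen$modeling_network, corr, ms, cfg)
  expect_lt(fit$val_mse, 1e-8)   # solver-tolerance scale
  # max |contribution| small relative to max |h_kappa| along the trajectory
  tr <- dat$truth
  ctb <- contribution_series(fit$correction, tr, scen$generating_network)
  rhs <- build_rhs(scen$generating_network)
  hmax <- max(abs(t(apply(tr$states, 1, function(y) rhs(0, y)))))
  expect_lt(max(abs(ctb)) / hmax, 0.05)
})

test_that("curriculum fraction 1.0 collapses to a single phase", {
  scen <- toy_pulse_scenario(seed = 6, n_times = 7)
  ms <- generate_scenario_data(scen)$measurements
  corr <- init_correction(4, 8, seed = 6, measured = scen$measured)
  cfg <- training_config(n_train = 4, n_val = 2, steps_per_phase = 2,
                         batch_size = 4, seed = 6, curriculum = 1,
                         val_every = 2,
                         solver = solver_config("dopri5", rtol = 1e-4,
                                                atol = 1e-7))
  fit <- train(scen$modeling_network, corr, ms, cfg)
  expect_identical(attr(fit$report, "phases"), "full")
  expect_identical(nrow(fit$report), 2L)
  cfg$curriculum <- 0.1
  fit2 <- train(scen$modeling_network, corr, ms, cfg)
  expect_identical(attr(fit2$report, "phases"), c("curriculum", "full"))
  expect_identical(nrow(fit2$report), 4L)
})

test_that("training is deterministic given the seed", {
  scen <- hidden_interaction_scenario(toy_pulse_scenario(seed = 7, n_times = 9),
                                      "slow_inhibition", species = 7)
  ms <- generate_scenario_data(scen)$measurements
  corr <- init_correction(4, 8, seed = 7, measured = scen$measured)
  cfg <- training_config(n_train = 6, n_val = 3, steps_per_phase = 4,
                         batch_size = 4, seed = 7, val_every = 4,
                         solver = solver_config("dopri5", rtol = 1e-4,
                                                atol = 1e-7))
  f1 <- train(scen$modeling_network, corr, ms, cfg)
  f2 <- train(scen$modeling_network, corr, ms, cfg)
  expect_identical(theta_get(f1$correction), theta_get(f2$correction))
  expect_identical(f1$report$train_mse, f2$report$train_mse)
  expect_identical(f1$val_mse, f2$val_mse)
})

test_that("train/validation splits come from disjoint seed streams", {
  scen <- toy_pulse_scenario(seed = 8, n_times = 5)
  ms <- generate_scenario_data(scen)$measurements
  a <- sample_dataset(ms, 5, seed = 8)
  b <- sample_dataset(ms, 5, seed = 9)
  expect_false(identical(a$samples, b$samples))
})
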