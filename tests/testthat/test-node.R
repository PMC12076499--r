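test_that("zero correction leaves the mechanistic RHS untouched", {
  toy <- toy_oscillator()
  corr <- init_correction(4, 32, seed = 1, measured = c(1, 2, 6, 7))
  rhs0 <- build_rhs(toy$network)
  rhs_aug <- augmented_rhs(toy$network, corr)
  set.seed(5)
  for (i in 1:20) {
    y <- random_nonneg_state(7)
    expect_equal(rhs_aug(0, y), rhs0(0, y))
  }
  # with flow
  rhs0f <- apply_flow(rhs0, toy$flow)
  rhs_augf <- augmented_rhs(toy$network, corr, toy$flow)
  for (i in 1:10) {
    y <- random_nonneg_state(7)
    expect_equal(rhs_augf(0, y), rhs0f(0, y))
  }
})

test_that("augmented RHS is the additive decomposition h + P f", {
  toy <- toy_oscillator()
  meas <- c(1, 2, 6, 7)
  corr <- init_correction(4, 16, seed = 2, measured = meas,
                          x_scale = rep(0.1, 4))
  corr <- theta_set(corr, rnorm(length(theta_get(corr))) * 0.2)
  rhs0 <- build_rhs(toy$network)
  rhs_aug <- augmented_rhs(toy$network, corr)
  set.seed(6)
  for (i in 1:20) {
    y <- random_nonneg_state(7)
    d <- rhs_aug(0, y) - rhs0(0, y)
    expect_equal(d[meas], eval_correction(corr, y[meas]), tolerance = 1e-12)
    # unmeasured (and constant) species derivatives are untouched
    expect_identical(d[-meas], rep(0, 3))
  }
})

test_that("measured species must map into the network and not be constant", {
  toy <- toy_oscillator()
  expect_error(augmented_rhs(toy$network,
                             init_correction(2, 8, measured = c(1, 9))),
               "out of range")
  expect_error(augmented_rhs(toy$network,
                             init_correction(2, 8, measured = c(1, 5))),
               "constant")
})

test_that("contribution series equals augmented minus mechanistic derivative", {
  toy <- toy_oscillator()
  meas <- c(1, 2, 6, 7)
  corr <- init_correction(4, 16, seed = 3, measured = meas,
                          x_scale = rep(0.1, 4))
  corr <- theta_set(corr, rnorm(length(theta_get(corr))) * 0.1)
  rhs0 <- build_rhs(toy$network)
  rhs_aug <- augmented_rhs(toy$network, corr)
  tr <- solve_ivp(rhs_aug, toy$y0_batch, seq(0, 3, by = 0.25),
                  species = toy$network$species$name)
  ctb <- contribution_series(corr, tr, toy$network)
  for (i in seq_along(tr$times)) {
    y <- tr$states[i, ]
    expect_equal(ctb[i, ], (rhs_aug(0, y) - rhs0(0, y))[meas],
                 ignore_attr = TRUE, tolerance = 1e-14)
  }
  # zero correction -> identically zero series
  ctb0 <- contribution_series(init_correction(4, 32, measured = meas), tr,
                              toy$network)
  expect_true(all(ctb0 == 0))
})

test_that("zero-network equivalence holds through a solve", {
  toy <- toy_oscillator()
  corr <- init_correction(4, 32, seed = 4, measured = c(1, 2, 6, 7))
  cfg <- solver_config(rtol = 1e-8, atol = 1e-11)
  tt <- seq(0, toy$horizon_batch, length.out = 25)
  tr_theory <- solve_ivp(build_rhs(toy$network), toy$y0_batch, tt, cfg)
  tr_node <- solve_ivp(augmented_rhs(toy$network, corr), toy$y0_batch, tt, cfg)
  expect_equal(tr_node$states, tr_theory$states, tolerance = 1e-6)
})

test_that("adjoint gradient matches finite differences through the solve", {
  skip_if_not_installed("numDeriv")
  toy <- toy_oscillator()
  net <- toy$network
  meas <- c(1, 2, 6, 7)
  set.seed(42)
  corr <- init_correction(4, 8, seed = 3, measured = meas,
                          x_scale = c(0.05, 0.1, 0.05, 0.05))
  th <- theta_get(corr) + rnorm(length(theta_get(corr))) * 0.02
  corr <- theta_set(corr, th)
  Y0 <- rbind(toy$y0_batch, toy$y0_batch * c(1.2, 0.9, 1.1, 1, 1, 1, 1))
  obs_times <- seq(0, 2, length.out = 6)
  obs <- array(0, c(2, 6, 4))
  for (b in 1:2) {
    tr <- solve_ivp(build_rhs(net), Y0[b, ], obs_times)
    obs[b, , ] <- tr$states[, meas] + 0.002 * rnorm(24)
  }
  cfg <- solver_config("esdirk3", rtol = 1e-8, atol = 1e-10)
  res <- node_loss_grad(net, corr, Y0, obs_times, obs, config = cfg)
  lossfun <- function(i, x) {
    t2 <- th; t2[i] <- x
    node_loss_grad(net, theta_set(corr, t2), Y0, obs_times, obs,
                   config = cfg, want_grad = FALSE)$loss
  }
  idx <- c(50, length(th) - 30, length(th))   # cell weight, readout, bias
  for (i in idx) {
    fd <- numDeriv::grad(function(x) lossfun(i, x), th[i])
    expect_equal(res$grad_theta[i], fd, tolerance = 1e-3)
  }
  # kappa gradient
  fk <- function(x) {
    n2 <- net; n2$kappa["k_ac"] <- x
    node_loss_grad(n2, corr, Y0, obs_times, obs, config = cfg,
                   want_grad = FALSE)$loss
  }
  fd_k <- numDeriv::grad(fk, unname(net$kappa["k_ac"]))
  expect_equal(unname(res$grad_kappa["k_ac"]), fd_k, tolerance = 1e-3)
})

test_that("compiled dopri5 training path agrees with the reference path", {
  toy <- toy_oscillator()
  net <- toy$network
  meas <- c(1, 2, 6, 7)
  set.seed(1)
  corr <- init_correction(4, 32, seed = 3, measured = meas,
                          x_scale = c(0.05, 0.1, 0.05, 0.05))
  corr <- theta_set(corr, theta_get(corr) + rnorm(length(theta_get(corr))) * 0.01)
  B <- 4
  Y0 <- matrix(rep(toy$y0_batch, each = B), B, 7) *
    (1 + 0.05 * matrix(rnorm(B * 7), B, 7))
  obs_times <- seq(0, 2, length.out = 8)
  obs <- array(0.05, c(B, 8, 4))
  for (flow in list(NULL, toy$flow)) {
    ref <- node_loss_grad(net, corr, Y0, obs_times, obs, flow = flow,
                          config = solver_config("esdirk3", rtol = 1e-9,
                                                 atol = 1e-12))
    fast <- node_loss_grad(net, corr, Y0, obs_times, obs, flow = flow,
                           config = solver_config("dopri5", rtol = 1e-7,
                                                  atol = 1e-10))
    expect_equal(fast$loss, ref$loss, tolerance = 1e-5)
    expect_equal(fast$grad_theta, ref$grad_theta, tolerance = 1e-3)
    expect_equal(fast$grad_kappa, ref$grad_kappa, tolerance = 1e-3)
  }
})
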