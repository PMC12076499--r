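make_traj <- function(f, horizon = 40, dt = 0.01) {
  t <- seq(0, horizon, by = dt)
  trajectory(t, cbind(x = f(t)), time_unit = "h")
}

test_that("period estimator is exact on analytic sinusoids", {
  tr <- make_traj(function(t) sin(2 * pi * t / 3.5), horizon = 40, dt = 0.02)
  p <- estimate_period(tr, species = 1)
  expect_lt(abs(p - 3.5), 0.02)  # within the sampling grid
  expect_identical(classify_oscillation(tr, 1)[1], "sustained")
})

test_that("damped analytic signal: period and decay detected", {
  tr <- make_traj(function(t) 5 + exp(-t / 10) * sin(2 * pi * t / 2),
                  horizon = 30, dt = 0.01)
  p <- estimate_period(tr, 1)
  expect_lt(abs(p - 2), 0.02)
  cls <- classify_oscillation(tr, 1)
  expect_identical(cls[1], "damped")
  a <- attr(cls, "analysis")
  # amplitude decay over one 2 h cycle of exp(-t/10): factor exp(-0.2)
  expect_equal(a$decay_ratio, exp(-2 / 10), tolerance = 0.02)
})

test_that("monotone relaxation and flat signals are 'none'", {
  tr <- make_traj(function(t) 1 - exp(-t), horizon = 20, dt = 0.05)
  expect_identical(classify_oscillation(tr, 1)[1], "none")
  expect_true(is.na(estimate_period(tr, 1)))
  tr2 <- make_traj(function(t) rep(0.3, length(t)))
  expect_identical(classify_oscillation(tr2, 1)[1], "none")
})

test_that("estimator is invariant to vertical scaling and offset", {
  f <- function(t) sin(2 * pi * t / 3.1) + 0.2 * sin(4 * pi * t / 3.1)
  tr1 <- make_traj(f)
  tr2 <- make_traj(function(t) 7 + 40 * f(t))
  expect_equal(estimate_period(tr1, 1), estimate_period(tr2, 1))
  expect_identical(classify_oscillation(tr1, 1)[1],
                   classify_oscillation(tr2, 1)[1])
})

test_that("classification is monotone in the decay threshold", {
  tr <- make_traj(function(t) 2 + exp(-t / 25) * sin(2 * pi * t / 3))
  classes <- sapply(c(0.5, 0.9, 0.97, 0.999), function(thr)
    classify_oscillation(tr, 1,
                         thresholds = oscillation_thresholds(decay_ratio = thr))[1])
  # raising the threshold can only move sustained -> damped, never back
  sustained <- classes == "sustained"
  expect_true(all(diff(as.integer(sustained)) <= 0))
})

test_that("toy limit cycle period agrees with the spectral oracle", {
  toy <- toy_oscillator()
  rhs <- apply_flow(build_rhs(toy$network), toy$flow)
  tt <- seq(0, toy$horizon_flow, by = 0.02)
  tr <- solve_ivp(rhs, toy$y0_flow, tt,
                  solver_config("dopri5", rtol = 1e-7, atol = 1e-10),
                  species = toy$network$species$name)
  p_peaks <- estimate_period(tr, species = 6)
  keep <- tt >= 0.3 * toy$horizon_flow
  p_fft <- spectral_period(tt[keep], tr$states[keep, 6])
  expect_lt(abs(p_peaks - p_fft) / p_fft, 0.02)
  expect_identical(classify_oscillation(tr, 6)[1], "sustained")
  # long-horizon CSTR solve stays bounded and non-negative (to tolerance)
  expect_gt(min(tr$states), -1e-8)
  expect_lt(max(tr$states), max(toy$flow$y_in) * 1.5)
})

test_that("1x1 scan equals a direct classify + period call", {
  toy <- toy_oscillator()
  cfg <- solver_config("dopri5", rtol = 1e-6, atol = 1e-9)
  pd <- scan_phase_space(toy$network, 0.15, 2.5, toy$flow, toy$y0_flow,
                         horizon = toy$horizon_flow, config = cfg)
  expect_identical(nrow(pd), 1L)
  tr <- solve_ivp(apply_flow(build_rhs(toy$network), toy$flow), toy$y0_flow,
                  seq(0, toy$horizon_flow, by = 0.05), cfg)
  expect_identical(pd$class, classify_oscillation(tr, 6)[1])
  expect_equal(pd$period_h, estimate_period(tr, 6), tolerance = 1e-8)
})

test_that("diff_phase_diagrams subtracts periods where both sustained", {
  toy <- toy_oscillator()
  cfg <- solver_config("dopri5", rtol = 1e-5, atol = 1e-8)
  pd <- scan_phase_space(toy$network, c(0.1, 0.15), c(2.0, 2.5), toy$flow,
                         toy$y0_flow, horizon = 25, config = cfg)
  d0 <- diff_phase_diagrams(pd, pd)
  expect_true(all(d0$dperiod_h[pd$class == "sustained"] == 0))
  expect_true(all(is.na(d0$dperiod_h[pd$class != "sustained"])))
  pd2 <- pd
  pd2$period_h <- pd2$period_h + 0.5
  d <- diff_phase_diagrams(pd2, pd)
  expect_true(all(abs(d$dperiod_h[!is.na(d$dperiod_h)] - 0.5) < 1e-12))
  pd3 <- scan_phase_space(toy$network, c(0.1, 0.2), c(2.0, 2.5), toy$flow,
                          toy$y0_flow, horizon = 25, config = cfg)
  expect_error(diff_phase_diagrams(pd, pd3), "different grids")
})

test_that("period_table equals independent per-setting calls", {
  toy <- toy_oscillator()
  cfg <- solver_config("dopri5", rtol = 1e-5, atol = 1e-8)
  settings <- data.frame(fmoc_in_M = c(0.12, 0.15), pa_in_M = c(2.5, 2.5))
  tab <- period_table(list(theory = toy$network), settings, toy$flow,
                      toy$y0_flow, horizon = 25, config = cfg)
  expect_identical(names(tab), c("fmoc_in_M", "pa_in_M", "theory"))
  for (i in 1:2) {
    y_in <- toy$flow$y_in
    y_in[2] <- settings$fmoc_in_M[i]; y_in[4] <- settings$pa_in_M[i]
    tr <- solve_ivp(apply_flow(build_rhs(toy$network),
                               flow_conditions(y_in, toy$flow$D)),
                    toy$y0_flow, seq(0, 25, by = 0.05), cfg)
    expect_equal(tab$theory[i], estimate_period(tr, 6), tolerance = 1e-10)
  }
})
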