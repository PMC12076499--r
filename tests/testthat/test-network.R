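test_that("build_rhs reproduces simple mass-action systems by hand", {
  # A -> B, k = 2, first order
  rhs <- build_rhs(net_first_order(k = 2))
  expect_equal(rhs(0, c(1, 0)), c(-2, 2))
  # A + B -> 2B, k = 1, autocatalytic bimolecular step
  rhs2 <- build_rhs(net_autocatalytic(k = 1))
  expect_equal(rhs2(0, c(1, 1)), c(-1, 1))
  # batched evaluation agrees with the vector path
  Y <- rbind(c(1, 0), c(0.3, 0.7), c(2, 5))
  expect_equal(rhs(0, Y), t(apply(Y, 1, function(y) rhs(0, y))))
})

test_that("generic builder matches the hand-transcribed oscillator ODEs", {
  kappa <- c(k_tr = 5, k_ac = 300, k_inh1 = 1700, k_inh2 = 3)
  net <- fmoc_network(kappa)
  rhs <- build_rhs(net)
  oracle <- fmoc_rhs_oracle(kappa)
  set.seed(42)
  for (i in 1:100) {
    y <- random_nonneg_state(7, scale = 2)
    expect_equal(rhs(0, y), oracle(0, y), tolerance = 1e-12)
  }
})

test_that("rates are nonnegative on nonnegative states", {
  net <- toy_oscillator()$network
  set.seed(7)
  for (i in 1:50) {
    y <- random_nonneg_state(7, scale = 3)
    expect_true(all(reaction_rates(net, y) >= 0))
  }
})

test_that("constant species have zero derivative and validated stoichiometry", {
  net <- fmoc_network(c(k_tr = 1, k_ac = 1, k_inh1 = 1, k_inh2 = 1))
  rhs <- build_rhs(net)
  set.seed(1)
  for (i in 1:20) expect_identical(rhs(0, random_nonneg_state(7))[5], 0)
  # a constant species with nonzero net stoichiometry is rejected
  sp <- data.frame(index = 1:2, name = c("A", "B"),
                   constant = c(FALSE, TRUE))
  expect_error(
    crn_network(sp, list(reaction(c(A = 1), c(B = 1), "k")), c(k = 1)),
    "constant species")
})

test_that("unknown rate-constant keys are configuration errors", {
  sp <- data.frame(index = 1:2, name = c("A", "B"), constant = FALSE)
  expect_error(
    crn_network(sp, list(reaction(c(A = 1), c(B = 1), "k_missing")),
                c(k = 1)),
    "k_missing")
  net <- fmoc_network()  # terharmsel2023 placeholder: NA rate constants
  expect_error(build_rhs(net), "NA")
})

test_that("apply_flow implements the CSTR balance", {
  net <- net_zero_reactions(3)
  rhs <- build_rhs(net)
  fl <- flow_conditions(y_in = c(1, 2, 0.5), D = 0.7)
  frhs <- apply_flow(rhs, fl)
  # inflow balances outflow at y = y_in
  expect_equal(frhs(0, fl$y_in), rep(0, 3))
  # closed-form washout from y0 = 0: y(t) = y_in (1 - exp(-D t))
  tr <- solve_ivp(frhs, rep(0, 3), seq(0, 5, by = 0.25),
                  solver_config(rtol = 1e-9, atol = 1e-12))
  expected <- outer(1 - exp(-0.7 * tr$times), fl$y_in)
  expect_equal(tr$states, expected, tolerance = 1e-7,
               ignore_attr = TRUE)
  # D = 0 reduces to the batch dynamics
  net2 <- toy_oscillator()$network
  rhs2 <- build_rhs(net2)
  frhs2 <- apply_flow(rhs2, flow_conditions(rep(0.1, 7), D = 0))
  set.seed(3)
  for (i in 1:20) {
    y <- random_nonneg_state(7)
    expect_equal(frhs2(0, y), rhs2(0, y))
  }
  # dimension mismatch errors
  expect_error(apply_flow(rhs2, flow_conditions(c(1, 2), 1)), "species")
})

test_that("ablate_reaction removes a term from selected species only", {
  toy <- toy_oscillator()
  net <- toy$network
  abl <- ablate_reaction(net, "slow_inhibition", species = 7)
  rhs_full <- build_rhs(net)
  rhs_abl <- build_rhs(abl)
  k2 <- net$kappa["k_inh2"]
  set.seed(11)
  for (i in 1:25) {
    y <- random_nonneg_state(7)
    d_full <- rhs_full(0, y)
    d_abl <- rhs_abl(0, y)
    # d[7]/dt loses exactly the k_inh2 y1 y4 term
    expect_equal(d_full[7] - d_abl[7], unname(k2 * y[1] * y[4]),
                 tolerance = 1e-12)
    # the rest of the system is unaltered
    expect_equal(d_full[-7], d_abl[-7])
  }
  # full removal then re-addition restores the original RHS
  removed <- ablate_reaction(net, "slow_inhibition")
  expect_equal(length(removed$reactions), 3L)
  readded <- crn_network(removed$species,
                         c(removed$reactions,
                           net$reactions[net$labels == "slow_inhibition"]),
                         net$kappa)
  rhs_back <- build_rhs(readded)
  for (i in 1:10) {
    y <- random_nonneg_state(7)
    expect_equal(rhs_back(0, y), rhs_full(0, y), tolerance = 1e-12)
  }
  expect_error(ablate_reaction(net, "nope"), "unknown reaction")
})

test_that("conserved_moieties returns the left null space", {
  # {A -> B}: total mass conserved
  W <- conserved_moieties(net_first_order())
  expect_equal(ncol(W), 1L)
  expect_equal(unname(W[1, 1]), unname(W[2, 1]), tolerance = 1e-12)
  # {A + B -> 2B}: (1, 1) in the null space
  W2 <- conserved_moieties(net_autocatalytic())
  expect_equal(abs(sum(c(1, 1) * W2[, 1])) / sqrt(2), 1, tolerance = 1e-12)
  # oscillator: every basis vector annihilates S, and the numerically
  # computed null space contains a vector supported on the
  # piperidine-bearing species {1, 2, 7}
  net <- toy_oscillator()$network
  W3 <- conserved_moieties(net)
  S <- stoichiometry_matrix(net)
  expect_true(all(abs(t(W3) %*% S) < 1e-12))
  # oracle: svd-based null space of the independently transcribed S
  S_oracle <- matrix(0, 7, 4)
  S_oracle[, 1] <- c(1, -1, 0, 0, 0, 1, 0)    # trigger
  S_oracle[, 2] <- c(1, -1, 0, 0, 0, 1, 0)    # autocatalysis
  S_oracle[, 3] <- c(-1, 0, -1, 0, 0, 0, 1)   # fast inhibition
  S_oracle[, 4] <- c(-1, 0, 0, -1, 0, 0, 1)   # slow inhibition
  expect_equal(S, S_oracle, ignore_attr = TRUE)
  w_pip <- c(1, 1, 0, 0, 0, 0, 1)             # piperidine backbone
  # w_pip lies in the span of the returned basis
  resid <- w_pip - W3 %*% (t(W3) %*% w_pip)
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("unit rescaling leaves trajectories invariant", {
  toy <- toy_oscillator()
  net_h <- toy$network                    # hours
  net_s <- rescale_time_unit(net_h, "s")  # seconds
  expect_equal(net_s$kappa, net_h$kappa / 3600)
  t_h <- seq(0, 2, by = 0.2)
  tr_h <- solve_ivp(build_rhs(net_h), toy$y0_batch, t_h,
                    solver_config(rtol = 1e-9, atol = 1e-12))
  tr_s <- solve_ivp(build_rhs(net_s), toy$y0_batch, t_h * 3600,
                    solver_config(rtol = 1e-9, atol = 1e-12))
  expect_equal(tr_h$states, tr_s$states, tolerance = 1e-6)
  # round trip restores the constants exactly
  expect_equal(rescale_time_unit(net_s, "h")$kappa, net_h$kappa)
})
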