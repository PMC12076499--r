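#' Synthetic-data scenario
#'
#' A scenario fixes everything needed to generate data and to model it: the
#' generating (ground-truth) network, the modeling network (possibly with a
#' reaction pathway ablated, emulating a hidden interaction), the reactor mode,
#' initial/flow conditions, the measurement protocol and the noise model.
#'
#' @param generating_network ground-truth [crn_network()] used to simulate.
#' @param modeling_network network handed to the modeler; defaults to the
#'   generating network (a well-specified model).
#' @param mode `"batch"` (closed reactor) or `"flow"` (CSTR).
#' @param y0 initial concentrations (all species).
#' @param flow [flow_conditions()]; required when `mode = "flow"`.
#' @param measurement_times increasing times at which measurements are taken.
#' @param measured indices of measured species.
#' @param noise_sd absolute measurement noise s.d. per species (scalar
#'   recycled, or length-M vector), in concentration units.
#' @param replicates number of replicate measurements (default 2, the
#'   experimental practice this emulates).
#' @param seed integer seed for the noise draws.
#' @return object of class `crn_scenario`.
#' @export
scenario <- function(generating_network, modeling_network = generating_network,
                     mode = c("batch", "flow"), y0, flow = NULL,
                     measurement_times, measured, noise_sd = 0,
                     replicates = 2L, seed = 1L) {
  mode <- match.arg(mode)
  M <- nrow(generating_network$species)
  y0 <- as.numeric(y0)
  stopifnot(length(y0) == M, all(y0 >= 0))
  if (mode == "flow" && is.null(flow)) stop("flow mode requires flow conditions")
  measurement_times <- as.numeric(measurement_times)
  if (any(diff(measurement_times) <= 0))
    stop("measurement_times must be strictly increasing")
  noise_sd <- rep_len(as.numeric(noise_sd), M)
  if (any(noise_sd < 0)) stop("noise sd must be nonnegative")
  if (is.logical(measured)) measured <- which(measured)
  structure(list(generating_network = generating_network,
                 modeling_network = modeling_network, mode = mode,
                 y0 = y0, flow = if (mode == "flow") flow,
                 measurement_times = measurement_times,
                 measured = as.integer(measured), noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "crn_scenario")
}

#' Simulate the ground truth of a scenario
#'
#' Deterministic tight-tolerance solve (rtol 1e-9) of the generating network
#' under the scenario's reactor conditions.
#'
#' @param scen a [scenario()].
#' @param save_times optional save grid; defaults to a dense grid (20 points
#'   per measurement interval) covering the measurement horizon, so the
#'   trajectory can also feed oscillation analysis.
#' @param config solver settings; default `esdirk3` at rtol 1e-9 / atol 1e-12.
#' @return a [trajectory()].
#' @export
simulate_ground_truth <- function(scen, save_times = NULL,
                                  config = solver_config("esdirk3",
                                                         rtol = 1e-9,
                                                         atol = 1e-12)) {
  stopifnot(inherits(scen, "crn_scenario"))
  net <- scen$generating_network
  rhs <- build_rhs(net)
  if (scen$mode == "flow") rhs <- apply_flow(rhs, scen$flow)
  if (is.null(save_times)) {
    mt <- scen$measurement_times
    save_times <- sort(unique(c(mt, seq(mt[1], mt[length(mt)],
                                        length.out = 20 * (length(mt) - 1) + 1))))
  }
  solve_ivp(rhs, scen$y0, save_times,
            config = config, species = net$species$name,
            time_unit = net$time_unit,
            jac = mass_action_jacobian(net))
}

#' Turn a trajectory into replicated noisy measurements
#'
#' Each replicate is the true concentration plus independent Gaussian noise
#' (s.d. per species), truncated at zero; the emitted series carries the mean
#' and the sample standard deviation (denominator `n - 1`; for two replicates
#' `std = |r1 - r2| / sqrt(2)`) across replicates. Unmeasured species keep
#' their true values with zero std, so initial conditions remain available to
#' the modeler.
#'
#' @param traj a [trajectory()] of the ground truth.
#' @param noise_sd absolute s.d. per species (scalar or length-M).
#' @param replicates >= 2 for a nonzero std (>= 1 accepted).
#' @param times measurement times; must lie within the trajectory's span
#'   (values between grid points are linearly interpolated).
#' @param measured indices of measured species.
#' @param seed integer seed.
#' @return a [measurement_series()].
#' @export
make_measurements <- function(traj, noise_sd, replicates = 2L,
                              times = traj$times,
                              measured = seq_len(ncol(traj$states)),
                              seed = 1L) {
  M <- ncol(traj$states)
  noise_sd <- rep_len(as.numeric(noise_sd), M)
  times <- as.numeric(times)
  if (min(times) < traj$times[1] - 1e-12 ||
      max(times) > traj$times[length(traj$times)] + 1e-12)
    stop("requested measurement times outside the trajectory span")
  if (is.logical(measured)) measured <- which(measured)
  truth <- vapply(seq_len(M), function(k)
    stats::approx(traj$times, traj$states[, k], xout = times)$y,
    numeric(length(times)))
  truth <- matrix(truth, length(times), M)
  Tn <- length(times)
  out <- with_local_seed(seed, {
    mu <- truth; sdm <- matrix(0, Tn, M)
    for (k in measured) {
      if (noise_sd[k] > 0) {
        reps <- matrix(stats::rnorm(Tn * replicates, truth[, k], noise_sd[k]),
                       Tn, replicates)
        reps <- pmax(reps, 0)
        mu[, k] <- rowMeans(reps)
        sdm[, k] <- apply(reps, 1, stats::sd)
      } else if (replicates >= 2) {
        sdm[, k] <- 0
      }
    }
    list(mu = mu, sdm = sdm)
  })
  measurement_series(times, out$mu, out$sdm, measured,
                     time_unit = traj$time_unit)
}

#' Hidden-interaction scenario
#'
#' Builds the data/model mismatch construct used to probe hidden reactions:
#' data are generated by the full network while the modeler receives an
#' ablated copy (a reaction removed entirely, or its contribution removed from
#' selected species' equations only).
#'
#' @param base_scenario a [scenario()] whose generating network is the full
#'   model.
#' @param label reaction label to ablate in the modeling network.
#' @param species optional species restriction, as in [ablate_reaction()];
#'   `NULL` removes the whole reaction. An empty ablation (`label = NULL`)
#'   returns the scenario unchanged (the null scenario).
#' @return the modified [scenario()].
#' @export
hidden_interaction_scenario <- function(base_scenario, label,
                                        species = NULL) {
  stopifnot(inherits(base_scenario, "crn_scenario"))
  if (is.null(label)) return(base_scenario)
  base_scenario$modeling_network <-
    ablate_reaction(base_scenario$generating_network, label, species)
  base_scenario
}

#' Generate a measurement series from a scenario
#'
#' Convenience wrapper: simulate the ground truth, then measure it with the
#' scenario's noise model.
#'
#' @param scen a [scenario()].
#' @return list with `truth` (dense [trajectory()]) and `measurements`
#'   (a [measurement_series()]).
#' @export
generate_scenario_data <- function(scen) {
  truth <- simulate_ground_truth(scen)
  ms <- make_measurements(truth, scen$noise_sd, scen$replicates,
                          times = scen$measurement_times,
                          measured = scen$measured, seed = scen$seed)
  list(truth = truth, measurements = ms)
}

#' Canonical single-pulse training scenario on the toy oscillator
#'
#' A closed-reactor pulse experiment emulating the aperiodic single-pulse
#' data: four measured species (piperidine, Fmoc-piperidine, dibenzofulvene,
#' N-acetyl piperidine), 25 measurement times over the pulse, two replicates,
#' and absolute Gaussian noise of 2 mM on the measured species.
#'
#' @param seed seed for the measurement noise.
#' @param n_times number of measurement times.
#' @return a [scenario()].
#' @export
toy_pulse_scenario <- function(seed = 1L, n_times = 25L) {
  toy <- toy_oscillator()
  measured <- c(1L, 2L, 6L, 7L)
  sd <- numeric(7); sd[measured] <- 0.002
  scenario(toy$network, mode = "batch", y0 = toy$y0_batch,
           measurement_times = seq(0, toy$horizon_batch,
                                   length.out = n_times),
           measured = measured, noise_sd = sd, replicates = 2L, seed = seed)
}
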