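#' Augment a mechanistic network with a neural correction
#'
#' Builds the right-hand side of the hybrid (universal) differential equation
#' `dy/dt = h_kappa(t, y) [+ flow terms] + P f_theta(y_measured)`, where `P`
#' scatters the correction onto the measured species and leaves unmeasured and
#' constant species untouched.
#'
#' @param network a [crn_network()].
#' @param correction a [init_correction()] whose `measured` indices map into
#'   the network's species; measured species must not be constant.
#' @param flow optional [flow_conditions()] for an open (CSTR) reactor.
#' @return an RHS function with the same batch semantics as [build_rhs()].
#' @export
augmented_rhs <- function(network, correction, flow = NULL) {
  M <- nrow(network$species)
  meas <- correction$measured
  if (any(meas < 1 | meas > M))
    stop("measured species indices out of range for this network")
  if (any(network$species$constant[meas]))
    stop("measured species must not be constant: ",
         paste(network$species$name[meas][network$species$constant[meas]],
               collapse = ", "))
  base <- build_rhs(network)
  if (!is.null(flow)) base <- apply_flow(base, flow)
  f <- function(t, y) {
    dy <- base(t, y)
    if (is.matrix(y)) {
      dy[, meas] <- dy[, meas] + correction_forward(correction,
                                                    y[, meas, drop = FALSE])$out
    } else {
      dy[meas] <- dy[meas] + drop(correction_forward(correction,
                                                     matrix(y[meas], 1))$out)
    }
    dy
  }
  structure(f, n_species = M, constant = network$species$constant,
            measured = meas, class = c("crn_rhs", "function"))
}

# Analytic Jacobian of the augmented RHS (mechanistic + flow + correction),
# batched: (t, Y) -> B x M x M. Used by the implicit solver and the adjoint.
augmented_jacobian <- function(network, correction = NULL, flow = NULL) {
  mech <- mass_action_jacobian(network)
  const <- network$species$constant
  M <- nrow(network$species)
  meas <- if (!is.null(correction)) correction$measured
  function(t, y) {
    vec <- !is.matrix(y)
    Y <- if (vec) matrix(y, 1) else y
    J <- mech(t, Y)
    if (vec) J <- array(J, c(1, M, M))
    if (!is.null(flow) && flow$D > 0) {
      for (m in which(!const)) J[, m, m] <- J[, m, m] - flow$D
    }
    if (!is.null(correction)) {
      Jn <- correction_input_jacobian(correction, Y[, meas, drop = FALSE])
      J[, meas, meas] <- J[, meas, meas, drop = FALSE] + Jn
    }
    if (vec) J[1, , ] else J
  }
}

#' Neural contribution along a trajectory
#'
#' Evaluates the correction term at every saved state of a trajectory: the
#' per-species, per-time residual dynamics the network has learned on top of
#' the mechanistic model. Identically, the difference between the augmented
#' derivative and the mechanistic derivative at the same states.
#'
#' @param correction a [init_correction()] object.
#' @param traj a [trajectory()] whose columns cover the measured species.
#' @param network the [crn_network()] the trajectory refers to (used only for
#'   species naming).
#' @return matrix `length(times) x n_io` with one column per measured species;
#'   attribute `times` carries the time grid.
#' @export
contribution_series <- function(correction, traj, network = NULL) {
  Y <- traj$states[, correction$measured, drop = FALSE]
  out <- correction_forward(correction, Y)$out
  cn <- if (!is.null(network)) network$species$name[correction$measured]
        else colnames(traj$states)[correction$measured]
  colnames(out) <- cn
  attr(out, "times") <- traj$times
  out
}
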