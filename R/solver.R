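#' Solver configuration
#'
#' @param method `"esdirk3"` (default): stiffly accurate, L-stable 4-stage
#'   implicit Runge-Kutta pair of order 3(2) in the Kvaerno ESDIRK
#'   construction, suited to stiff mass-action systems. `"dopri5"`: explicit
#'   Dormand-Prince 5(4) for non-stiff problems.
#' @param rtol,atol relative/absolute tolerances (> 0).
#' @param initial_step optional first step size; chosen automatically if `NULL`.
#' @param max_steps cap on accepted + rejected steps before aborting.
#' @param dense keep all accepted steps so the solution can be interpolated
#'   between save points (needed by the adjoint gradient).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(method = c("esdirk3", "dopri5"), rtol = 1e-6,
                          atol = 1e-8, initial_step = NULL,
                          max_steps = 100000L, dense = FALSE) {
  method <- match.arg(method)
  stopifnot(rtol > 0, atol > 0, max_steps > 0)
  structure(list(method = method, rtol = rtol, atol = atol,
                 initial_step = initial_step,
                 max_steps = as.integer(max_steps), dense = dense),
            class = "solver_config")
}

# ---------------------------------------------------------------------------
# Butcher tableaus.
#
# The implicit pair is the 4-stage ESDIRK with an explicit first stage,
# stiffly accurate rows and diagonal gamma, where gamma is the middle root of
#   6 g^3 - 18 g^2 + 9 g - 1 = 0
# (the choice making the 3-stage SDIRK core L-stable). All remaining
# coefficients follow from the order conditions, so the tableau is *derived*
# here rather than copied: c = (0, 2g, 1, 1); stage 3 is the embedded
# second-order solution; row 4 (= b) satisfies the order-3 conditions.
# ---------------------------------------------------------------------------
.tableau_cache <- new.env(parent = emptyenv())

esdirk3_tableau <- function() {
  if (!is.null(.tableau_cache$esdirk3)) return(.tableau_cache$esdirk3)
  g <- stats::uniroot(function(x) 6 * x^3 - 18 * x^2 + 9 * x - 1,
                      c(0.3, 0.5), tol = 1e-15)$root
  a32 <- (1 / 2 - g) / (2 * g)
  a31 <- 1 - g - a32
  b2 <- 1 / (12 * g * (1 - 2 * g))
  b3 <- 1 / 2 - g - 2 * g * b2
  b1 <- 1 - g - b2 - b3
  A <- rbind(c(0, 0, 0, 0),
             c(g, g, 0, 0),
             c(a31, a32, g, 0),
             c(b1, b2, b3, g))
  tb <- list(A = A, b = A[4, ], b_err = A[4, ] - c(a31, a32, g, 0),
             c = c(0, 2 * g, 1, 1), order = 3, implicit = TRUE,
             gamma = g, fsal = TRUE)
  .tableau_cache$esdirk3 <- tb
  tb
}

dopri5_tableau <- function() {
  if (!is.null(.tableau_cache$dopri5)) return(.tableau_cache$dopri5)
  A <- matrix(0, 7, 7)
  A[2, 1] <- 1 / 5
  A[3, 1:2] <- c(3 / 40, 9 / 40)
  A[4, 1:3] <- c(44 / 45, -56 / 15, 32 / 9)
  A[5, 1:4] <- c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729)
  A[6, 1:5] <- c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656)
  A[7, 1:6] <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  b <- A[7, ]
  bh <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  tb <- list(A = A, b = b, b_err = b - bh, c = rowSums(A), order = 5,
             implicit = FALSE, gamma = 0, fsal = TRUE)
  .tableau_cache$dopri5 <- tb
  tb
}

get_tableau <- function(method) {
  switch(method, esdirk3 = esdirk3_tableau(), dopri5 = dopri5_tableau(),
         stop("unknown solver method: ", method))
}

# Finite-difference Jacobian of a batched RHS: (t, Y[BxM]) -> array B x M x M.
fd_jacobian <- function(rhs) {
  function(t, Y) {
    B <- nrow(Y); M <- ncol(Y)
    f0 <- rhs(t, Y)
    J <- array(0, c(B, M, M))
    for (s in seq_len(M)) {
      h <- 1e-7 * pmax(abs(Y[, s]), 1e-4)
      Yp <- Y
      Yp[, s] <- Yp[, s] + h
      J[, , s] <- (rhs(t, Yp) - f0) / h
    }
    J
  }
}

#' Low-level adaptive ODE integration (batched)
#'
#' Integrates `dY/dt = rhs(t, Y)` for a batch of initial states (rows of
#' `Y0`), hitting every entry of `save_times` exactly. Implicit methods use a
#' modified Newton iteration with a per-sample Jacobian (analytic if `jac` is
#' given, finite-difference otherwise). This is the engine behind
#' [solve_ivp()]; most users want that interface.
#'
#' @param rhs function `(t, Y)` with `Y` a `B x M` matrix, returning `B x M`.
#' @param Y0 `B x M` matrix of initial states.
#' @param t0 start time.
#' @param save_times strictly increasing times (>= t0) at which to record the
#'   solution.
#' @param config a [solver_config()].
#' @param jac optional analytic Jacobian `(t, Y) -> B x M x M` array.
#' @return list with `times`, `states` (array `B x T x M`), `steps` (accepted
#'   step mesh with states and derivatives when `config$dense`), and step
#'   statistics.
#' @keywords internal
#' @export
ode_integrate <- function(rhs, Y0, t0, save_times, config = solver_config(),
                          jac = NULL, jac_mean = FALSE) {
  Y0 <- as.matrix(Y0)
  B <- nrow(Y0); M <- ncol(Y0)
  save_times <- as.numeric(save_times)
  if (length(save_times) == 0) stop("save_times must be nonempty")
  if (any(diff(save_times) <= 0)) stop("save_times must be strictly increasing")
  if (save_times[1] < t0 - 1e-12 * max(1, abs(t0)))
    stop("save_times must not precede t0")
  tb <- get_tableau(config$method)
  if (tb$implicit && is.null(jac)) jac <- fd_jacobian(rhs)

  rtol <- config$rtol; atol <- config$atol
  t_end <- save_times[length(save_times)]
  out <- array(NA_real_, c(B, length(save_times), M))
  isave <- 1L
  if (abs(save_times[1] - t0) <= 1e-14 * max(1, abs(t0))) {
    out[, 1, ] <- Y0
    isave <- 2L
  }

  t <- t0
  Y <- Y0
  f_now <- rhs(t, Y)
  if (any(!is.finite(f_now)))
    stop("non-finite right-hand side at the initial state")

  # initial step: conservative power rule on the scaled derivative norm
  h <- config$initial_step
  if (is.null(h)) {
    sc <- atol + rtol * abs(Y)
    d0 <- sqrt(mean((Y / sc)^2)); d1 <- sqrt(mean((f_now / sc)^2))
    h <- if (d1 > 1e-10) 0.01 * d0 / d1 else 1e-6 * max(1, abs(t_end - t0))
    h <- min(h, abs(t_end - t0))
    if (h <= 0) h <- 1e-6
  }

  dense_t <- if (config$dense) numeric(0)
  dense_y <- if (config$dense) list()
  dense_f <- if (config$dense) list()
  if (config$dense) {
    dense_t <- t; dense_y[[1]] <- Y; dense_f[[1]] <- f_now
  }

  n_acc <- 0L; n_rej <- 0L; n_newton_fail <- 0L
  stages <- nrow(tb$A)
  err_exp <- 1 / (tb$order)          # embedded order = order - 1 -> 1/(q+1)
  safety <- 0.9

  while (t < t_end - 1e-14 * max(1, abs(t_end))) {
    if (n_acc + n_rej >= config$max_steps)
      stop(sprintf("ode_integrate: max_steps (%d) exceeded at t = %.6g",
                   config$max_steps, t))
    h <- min(h, t_end - t)
    # land exactly on the next save time
    if (isave <= length(save_times) && t + h > save_times[isave] - 1e-14)
      h <- save_times[isave] - t

    K <- vector("list", stages)
    failed <- FALSE
    W <- NULL  # per-sample inverse of (I - h*gamma*J), shared across stages
    for (i in seq_len(stages)) {
      ti <- t + tb$c[i] * h
      acc <- Y
      for (j in seq_len(i - 1)) if (tb$A[i, j] != 0)
        acc <- acc + (h * tb$A[i, j]) * K[[j]]
      aii <- tb$A[i, i]
      if (!tb$implicit || aii == 0) {
        K[[i]] <- if (i == 1) f_now else rhs(ti, acc)
        if (any(!is.finite(K[[i]]))) { failed <- TRUE; break }
        next
      }
      # Newton solve: Z = acc + h*aii*rhs(ti, Z). With jac_mean, a single
      # Newton matrix from the batch-mean state is shared by all samples
      # (modified Newton: only the convergence rate, never the solution,
      # depends on the matrix).
      if (is.null(W)) {
        if (jac_mean && B > 1) {
          Jm <- jac(t, matrix(colMeans(Y), 1))
          Wi <- try(base::solve(diag(M) - (h * aii) * matrix(Jm[1, , ], M, M)),
                    silent = TRUE)
          if (inherits(Wi, "try-error")) { failed <- TRUE; break }
          W <- list(shared = Wi)
        } else {
          J <- jac(t, Y)
          if (B == 1 && length(dim(J)) == 2) J <- array(J, c(1, M, M))
          W <- vector("list", B)
          ok <- TRUE
          for (bq in seq_len(B)) {
            Wi <- try(base::solve(diag(M) - (h * aii) * matrix(J[bq, , ], M, M)),
                      silent = TRUE)
            if (inherits(Wi, "try-error")) { ok <- FALSE; break }
            W[[bq]] <- Wi
          }
          if (!ok) { failed <- TRUE; break }
        }
      }
      shared_W <- !is.null(W$shared)
      Z <- acc + (h * aii) * (if (i == 2 && tb$c[1] == 0) f_now else rhs(ti, acc))
      conv <- FALSE
      for (it in seq_len(12)) {
        G <- Z - acc - (h * aii) * rhs(ti, Z)
        if (any(!is.finite(G))) break
        if (shared_W) {
          Z <- Z - G %*% t(W$shared)
        } else {
          for (bq in seq_len(B)) Z[bq, ] <- Z[bq, ] - W[[bq]] %*% G[bq, ]
        }
        sc <- atol + rtol * abs(Z)
        dn <- sqrt(mean((G / sc)^2))
        if (dn < 3e-2) { conv <- TRUE; break }
      }
      if (!conv) { failed <- TRUE; n_newton_fail <- n_newton_fail + 1L; break }
      K[[i]] <- rhs(ti, Z)
      if (any(!is.finite(K[[i]]))) { failed <- TRUE; break }
    }

    if (!failed) {
      Y1 <- Y
      for (i in seq_len(stages)) if (tb$b[i] != 0)
        Y1 <- Y1 + (h * tb$b[i]) * K[[i]]
      Eac <- matrix(0, B, M)
      for (i in seq_len(stages)) if (tb$b_err[i] != 0)
        Eac <- Eac + (h * tb$b_err[i]) * K[[i]]
      if (tb$implicit && !is.null(W)) {
        # damp stiff components of the embedded error estimate
        if (!is.null(W$shared)) {
          Eac <- Eac %*% t(W$shared)
        } else {
          for (bq in seq_len(B)) Eac[bq, ] <- W[[bq]] %*% Eac[bq, ]
        }
      }
      sc <- atol + rtol * pmax(abs(Y), abs(Y1))
      err <- sqrt(mean((Eac / sc)^2))
      if (!is.finite(err)) { failed <- TRUE } else if (err <= 1) {
        # accept
        t_new <- t + h
        f_new <- if (tb$fsal) K[[stages]] else rhs(t_new, Y1)
        while (isave <= length(save_times) &&
               save_times[isave] <= t_new + 1e-14 * max(1, abs(t_new))) {
          out[, isave, ] <- Y1   # we stepped exactly onto save times
          isave <- isave + 1L
        }
        t <- t_new; Y <- Y1; f_now <- f_new
        n_acc <- n_acc + 1L
        if (config$dense) {
          dense_t <- c(dense_t, t)
          dense_y[[length(dense_y) + 1L]] <- Y
          dense_f[[length(dense_f) + 1L]] <- f_now
        }
        h <- h * min(5, max(0.2, safety * err^(-err_exp)))
        next
      }
      # rejected on error
      n_rej <- n_rej + 1L
      h <- h * min(1, max(0.1, safety * err^(-err_exp)))
    } else {
      n_rej <- n_rej + 1L
      h <- h / 2
    }
    if (h < 1e-14 * max(1, abs(t_end)))
      stop(sprintf("ode_integrate: step size underflow at t = %.6g", t))
  }

  list(times = save_times, states = out,
       steps = if (config$dense)
         list(t = dense_t, y = dense_y, f = dense_f),
       n_accepted = n_acc, n_rejected = n_rej,
       n_newton_failures = n_newton_fail)
}

# Cubic Hermite interpolation over the accepted-step mesh returned by
# ode_integrate(..., dense = TRUE). Returns a function t -> B x M matrix.
dense_interpolant <- function(steps) {
  tt <- steps$t
  function(t) {
    n <- length(tt)
    if (t <= tt[1]) return(steps$y[[1]])
    if (t >= tt[n]) return(steps$y[[n]])
    i <- findInterval(t, tt)
    h <- tt[i + 1] - tt[i]
    s <- (t - tt[i]) / h
    h00 <- (1 + 2 * s) * (1 - s)^2
    h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s)
    h11 <- s^2 * (s - 1)
    h00 * steps$y[[i]] + (h10 * h) * steps$f[[i]] +
      h01 * steps$y[[i + 1]] + (h11 * h) * steps$f[[i + 1]]
  }
}

#' Trajectory container
#'
#' @param times increasing time vector.
#' @param states `length(times) x n_species` matrix of concentrations.
#' @param species character vector of species names (column names).
#' @param time_unit `"s"`, `"h"` or `"d"`.
#' @param metadata free-form list (model variant, seed, solver stats ...).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(times, states, species = colnames(states),
                       time_unit = "h", metadata = list()) {
  states <- as.matrix(states)
  times <- as.numeric(times)
  if (length(times) != nrow(states)) stop("times/states length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(states))) stop("states must be finite")
  if (!is.null(species)) colnames(states) <- species
  structure(list(times = times, states = states, time_unit = time_unit,
                 metadata = metadata), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points (",
      format(x$times[1]), " .. ", format(x$times[length(x$times)]), " ",
      x$time_unit, "), ", ncol(x$states), " species\n", sep = "")
  invisible(x)
}

#' Solve an initial value problem
#'
#' High-level interface around the adaptive integrator: solves
#' `dy/dt = rhs(t, y)` from `y0` and records the solution at `save_times`.
#'
#' @param rhs a right-hand side from [build_rhs()], [apply_flow()] or
#'   [augmented_rhs()] (any function accepting a batched state works).
#' @param y0 nonnegative initial state vector.
#' @param save_times strictly increasing save grid; the first entry may equal
#'   the initial time.
#' @param config a [solver_config()].
#' @param t0 initial time (defaults to `save_times[1]`).
#' @param species optional species names for the trajectory columns.
#' @param time_unit time unit recorded on the trajectory.
#' @param jac optional analytic Jacobian for the implicit solver.
#' @return a [trajectory()].
#' @export
solve_ivp <- function(rhs, y0, save_times, config = solver_config(),
                      t0 = save_times[1], species = NULL, time_unit = "h",
                      jac = NULL) {
  y0 <- as.numeric(y0)
  if (any(y0 < 0)) stop("y0 must be nonnegative elementwise")
  res <- ode_integrate(rhs, matrix(y0, 1), t0, save_times, config, jac = jac)
  st <- matrix(res$states[1, , ], length(save_times), length(y0))
  trajectory(save_times, st, species = species, time_unit = time_unit,
             metadata = list(n_accepted = res$n_accepted,
                             n_rejected = res$n_rejected,
                             method = config$method,
                             rtol = config$rtol, atol = config$atol))
}
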