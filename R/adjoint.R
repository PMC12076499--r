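# Continuous-adjoint gradient of a mean-squared-error loss of the nODE
# solution with respect to the correction parameters theta and the rate
# constants kappa.
#
# For L = mean_{b,i,k} (y_b(t_i)[k] - obs_b[i,k])^2 over measured species k,
# the adjoint state a(t) solves da/dt = -J(t, y)^T a backwards from the final
# observation, picking up a jump dL/dy(t_i) at every observation time, and
#   dL/dtheta = int_{t0}^{T} a(t)^T df/dtheta (t, y(t)) dt .
# The sweep below integrates the adjoint with the same ESDIRK pair as the
# forward solve (in tau = t_hi - t the dynamics are dm/dtau = +J^T m) and
# accumulates the parameter integral with Runge-Kutta stage quadrature: the
# integrand's vector-Jacobian products are harvested from the stage
# evaluations themselves, so the quadrature has the order of the method and
# costs one extra (cheap) kappa product per stage.

# Shared precomputations for one adjoint problem.
adjoint_context <- function(network, correction, flow) {
  k <- network$kappa[network$rate_keys]
  E <- network$E
  S <- network$S_eff
  R <- ncol(E)
  supp <- lapply(seq_len(R), function(j) which(E[, j] != 0))
  open_sp <- which(!network$species$constant)
  list(k = k, E = E, S = S, R = R, supp = supp,
       meas = correction$measured, corr = correction,
       D = if (is.null(flow)) 0 else flow$D, open_sp = open_sp,
       kappa_names = names(network$kappa), rate_keys = network$rate_keys,
       M = nrow(network$species))
}

# J(t, Y)^T L plus (optionally harvested) parameter VJPs.
# Y, L: B x M. Returns list(dL = B x M, gth = flat theta grad summed over the
# batch, gk = named kappa grad).
adjoint_eval <- function(ctx, Y, L, harvest = TRUE) {
  m <- cpp_ma_jtv(Y, L, ctx$k, ctx$E, ctx$S, harvest)
  out <- m$out
  if (ctx$D > 0)
    out[, ctx$open_sp] <- out[, ctx$open_sp] - ctx$D * L[, ctx$open_sp]
  fw <- correction_forward(ctx$corr, Y[, ctx$meas, drop = FALSE],
                           want_cache = TRUE)
  bw <- correction_backward(ctx$corr, fw$cache, L[, ctx$meas, drop = FALSE])
  out[, ctx$meas] <- out[, ctx$meas] + bw$dY
  gk <- NULL
  if (harvest) {
    gk <- stats::setNames(numeric(length(ctx$kappa_names)), ctx$kappa_names)
    for (j in seq_len(ctx$R))
      gk[ctx$rate_keys[j]] <- gk[ctx$rate_keys[j]] + m$gk[j]
  }
  list(dL = out, gth = if (harvest) bw$gth, gk = gk)
}

# Full J^T at the batch-mean state: M x M (for the Newton matrix).
adjoint_mean_jacobian <- function(ctx, jac_full, t, Y) {
  Jm <- jac_full(t, matrix(colMeans(Y), 1))
  t(matrix(Jm[1, , ], ctx$M, ctx$M))
}

# Integrate the adjoint over [t_lo, t_hi] (backwards in t), starting from L0
# at t_hi, accumulating the parameter quadrature. interp maps t -> B x M
# forward state. Returns list(L, gth, gk, n_accepted).
adjoint_interval <- function(ctx, jac_full, interp, t_lo, t_hi, L0,
                             rtol, atol, max_steps, h0 = NULL,
                             method = "esdirk3") {
  tb <- get_tableau(method)
  stages <- nrow(tb$A)
  err_exp <- 1 / tb$order
  Delta <- t_hi - t_lo
  B <- nrow(L0); M <- ncol(L0)
  tau <- 0
  L <- L0
  gth <- NULL; gk <- NULL
  ev <- adjoint_eval(ctx, interp(t_hi), L)
  f_now <- ev$dL; phi_now <- ev[c("gth", "gk")]
  # initial step: carried over from the previous interval when available,
  # otherwise a fraction of the interval bounded by the derivative scale
  if (!is.null(h0) && is.finite(h0) && h0 > 0) {
    h <- h0
  } else {
    sc <- atol + rtol * abs(L)
    d0 <- sqrt(mean((L / sc)^2)); d1 <- sqrt(mean((f_now / sc)^2))
    h <- if (d1 > 1e-10) min(0.01 * max(d0, 1) / d1, Delta) else Delta / 8
    if (h <= 0 || !is.finite(h)) h <- Delta / 8
  }
  n_acc <- 0L; n_tot <- 0L
  add_g <- function(g, phi, w) {
    if (is.null(g)) list(gth = w * phi$gth, gk = w * phi$gk)
    else list(gth = g$gth + w * phi$gth, gk = g$gk + w * phi$gk)
  }
  acc_g <- NULL
  while (tau < Delta - 1e-14 * max(1, Delta)) {
    n_tot <- n_tot + 1L
    if (n_tot > max_steps)
      stop("adjoint integration exceeded max_steps on [",
           format(t_lo), ", ", format(t_hi), "]")
    h <- min(h, Delta - tau)
    W <- NULL
    if (tb$implicit) {
      JT <- adjoint_mean_jacobian(ctx, jac_full, t_hi - tau,
                                  interp(t_hi - tau))
      W <- try(base::solve(diag(M) - (h * tb$gamma) * JT), silent = TRUE)
      if (inherits(W, "try-error")) { h <- h / 2; next }
    }
    K <- vector("list", stages)
    PHI <- vector("list", stages)
    K[[1]] <- f_now; PHI[[1]] <- phi_now
    failed <- FALSE
    for (i in 2:stages) {
      ti <- tau + tb$c[i] * h
      acc <- L
      for (j in seq_len(i - 1)) if (tb$A[i, j] != 0)
        acc <- acc + (h * tb$A[i, j]) * K[[j]]
      if (tb$A[i, i] == 0) {           # explicit stage
        evi <- adjoint_eval(ctx, interp(t_hi - ti), acc,
                            harvest = tb$b[i] != 0 || i == stages)
        K[[i]] <- evi$dL; PHI[[i]] <- evi[c("gth", "gk")]
        if (any(!is.finite(K[[i]]))) { failed <- TRUE; break }
        next
      }
      Z <- acc + (h * tb$A[i, i]) * K[[i - 1]]
      conv <- FALSE
      for (it in seq_len(12)) {
        Ft <- adjoint_eval(ctx, interp(t_hi - ti), Z, harvest = FALSE)$dL
        G <- Z - acc - (h * tb$A[i, i]) * Ft
        if (any(!is.finite(G))) break
        Z <- Z - G %*% t(W)
        sc <- atol + rtol * abs(Z)
        dn <- sqrt(mean((G / sc)^2))
        if (dn < 3e-2) { conv <- TRUE; break }
      }
      if (!conv) { failed <- TRUE; break }
      evi <- adjoint_eval(ctx, interp(t_hi - ti), Z)
      K[[i]] <- evi$dL; PHI[[i]] <- evi[c("gth", "gk")]
      if (any(!is.finite(K[[i]]))) { failed <- TRUE; break }
    }
    if (!failed) {
      L1 <- L
      for (i in seq_len(stages)) if (tb$b[i] != 0)
        L1 <- L1 + (h * tb$b[i]) * K[[i]]
      Eac <- matrix(0, B, M)
      for (i in seq_len(stages)) if (tb$b_err[i] != 0)
        Eac <- Eac + (h * tb$b_err[i]) * K[[i]]
      if (tb$implicit) Eac <- Eac %*% t(W)
      sc <- atol + rtol * pmax(abs(L), abs(L1))
      err <- sqrt(mean((Eac / sc)^2))
      if (is.finite(err) && err <= 1) {
        step_g <- NULL
        for (i in seq_len(stages)) if (tb$b[i] != 0)
          step_g <- add_g(step_g, PHI[[i]], h * tb$b[i])
        acc_g <- add_g(acc_g, step_g, 1)
        tau <- tau + h
        L <- L1
        f_now <- K[[stages]]; phi_now <- PHI[[stages]]   # FSAL
        n_acc <- n_acc + 1L
        h <- h * min(5, max(0.2, 0.9 * err^(-err_exp)))
        next
      }
      h <- h * min(1, max(0.1, 0.9 * (if (is.finite(err)) err else 10)^(-err_exp)))
    } else {
      h <- h / 2
    }
    if (h < 1e-14 * max(1, Delta))
      stop("adjoint step size underflow")
  }
  list(L = L, gth = if (is.null(acc_g)) 0 else acc_g$gth,
       gk = if (is.null(acc_g)) 0 else acc_g$gk, n_accepted = n_acc,
       h_last = h)
}

#' MSE loss and adjoint gradient of an nODE fit
#'
#' Solves the augmented system for a batch of initial states, evaluates the
#' masked mean-squared error against observations, and propagates the gradient
#' through the solve with the continuous adjoint method.
#'
#' @param network a [crn_network()].
#' @param correction a [init_correction()].
#' @param Y0 `B x M` matrix of initial states (one row per sample).
#' @param obs_times increasing observation times; `obs_times[1]` is the
#'   initial time.
#' @param obs `B x T x K` array of observed concentrations for the measured
#'   species (K = `correction$n_io`), on the `obs_times` grid.
#' @param flow optional [flow_conditions()].
#' @param config forward [solver_config()]; `dense` is forced on.
#' @param want_grad if `FALSE`, skip the adjoint pass and return the loss only.
#' @return list with `loss`, `grad_theta` (flat vector matching the trainable
#'   parameter layout), `grad_kappa` (named), and `pred` (`B x T x M`).
#' @keywords internal
#' @export
node_loss_grad <- function(network, correction, Y0, obs_times, obs,
                           flow = NULL, config = solver_config(),
                           want_grad = TRUE) {
  meas <- correction$measured
  Y0 <- as.matrix(Y0)
  B <- nrow(Y0); M <- ncol(Y0)
  Tn <- length(obs_times); K <- length(meas)
  stopifnot(all(dim(obs) == c(B, Tn, K)))
  if (config$method == "dopri5") {
    # compiled fast path (identical algorithm; cross-checked in the tests)
    k <- network$kappa[network$rate_keys]
    if (anyNA(k))
      stop("rate constant(s) not set (NA): ",
           paste(unique(network$rate_keys[is.na(k)]), collapse = ", "))
    res <- cpp_node_loss_grad(
      Y0, obs_times, obs, k, network$E, network$S_eff,
      correction$W, correction$b, correction$V, correction$c0,
      correction$x_scale, correction$out_scale, correction$measured,
      if (is.null(flow)) 0 else flow$D,
      if (is.null(flow)) numeric(M) else flow$y_in,
      which(!network$species$constant),
      config$rtol, config$atol, config$max_steps, want_grad)
    if (!want_grad) return(list(loss = res$loss, pred = res$pred))
    gk <- stats::setNames(numeric(length(network$kappa)),
                          names(network$kappa))
    for (j in seq_along(network$rate_keys))
      gk[network$rate_keys[j]] <- gk[network$rate_keys[j]] + res$grad_kappa[j]
    return(list(loss = res$loss, grad_theta = as.vector(res$grad_theta),
                grad_kappa = gk, pred = res$pred))
  }
  rhs <- augmented_rhs(network, correction, flow)
  jac <- augmented_jacobian(network, correction, flow)
  config$dense <- TRUE
  fwd <- ode_integrate(rhs, Y0, obs_times[1], obs_times, config, jac = jac,
                       jac_mean = B > 1)
  pred <- fwd$states
  resid <- pred[, , meas, drop = FALSE] - obs
  loss <- mean(resid^2)
  if (!want_grad)
    return(list(loss = loss, pred = pred))

  interp <- dense_interpolant(fwd$steps)
  ctx <- adjoint_context(network, correction, flow)
  dL_scale <- 2 / (B * Tn * K)
  n_theta <- length(theta_get(correction))
  g_theta <- numeric(n_theta)
  g_kappa <- stats::setNames(numeric(length(network$kappa)),
                             names(network$kappa))
  # integrate mu = lambda / dL_scale so the adjoint lives on the residual
  # scale and the forward tolerances remain meaningful
  L <- matrix(0, B, M)
  h_carry <- NULL
  for (i in Tn:2) {
    L[, meas] <- L[, meas] + matrix(resid[, i, ], B, K)
    sweep_res <- adjoint_interval(ctx, jac, interp, obs_times[i - 1],
                                  obs_times[i], L,
                                  rtol = config$rtol, atol = config$atol,
                                  max_steps = config$max_steps, h0 = h_carry,
                                  method = config$method)
    g_theta <- g_theta + sweep_res$gth
    g_kappa <- g_kappa + sweep_res$gk
    L <- sweep_res$L
    h_carry <- sweep_res$h_last
  }
  list(loss = loss, grad_theta = dL_scale * g_theta,
       grad_kappa = dL_scale * g_kappa, pred = pred)
}
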