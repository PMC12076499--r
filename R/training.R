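#' Measurement series container
#'
#' Per-time, per-species summary statistics of replicated concentration
#' measurements: the mean and standard deviation over replicates (two, for the
#' experiments this package emulates). Training samples are drawn from normal
#' distributions parametrized by these statistics.
#'
#' @param times increasing measurement times (first entry is the initial
#'   time of the experiment).
#' @param mean `T x M` matrix of mean concentrations, one column per species.
#' @param std `T x M` matrix of standard deviations (>= 0). Columns of
#'   unmeasured species are conventionally 0.
#' @param measured integer indices (or logical mask) of the measured species.
#' @param time_unit `"s"`, `"h"` or `"d"`.
#' @return object of class `measurement_series`.
#' @export
measurement_series <- function(times, mean, std, measured,
                               time_unit = "h") {
  times <- as.numeric(times)
  mean <- as.matrix(mean); std <- as.matrix(std)
  if (is.logical(measured)) measured <- which(measured)
  measured <- as.integer(measured)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(dim(mean) == dim(std))) stop("mean/std dimension mismatch")
  if (nrow(mean) != length(times)) stop("mean must have one row per time")
  if (any(!is.finite(mean))) stop("mean must be finite")
  if (any(std < 0)) stop("std must be nonnegative")
  if (length(measured) < 1) stop("at least one species must be measured")
  if (any(measured < 1 | measured > ncol(mean)))
    stop("measured indices out of range")
  structure(list(times = times, mean = mean, std = std,
                 measured = measured, time_unit = time_unit),
            class = "measurement_series")
}

#' @export
print.measurement_series <- function(x, ...) {
  cat("<measurement_series> ", length(x$times), " times, ", ncol(x$mean),
      " species (", length(x$measured), " measured), unit '",
      x$time_unit, "'\n", sep = "")
  invisible(x)
}

#' Draw synthetic sample time series from measurement statistics
#'
#' Every sample value is drawn independently as
#' `Normal(mean[t, k], std[t, k])`, truncated at zero (concentrations are
#' nonnegative); unmeasured species carry the mean series unchanged. Distinct
#' seeds give statistically independent datasets, which is how the
#' train/validation/test splits are kept disjoint.
#'
#' @param measurements a [measurement_series()].
#' @param n number of samples (>= 1).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return object of class `crn_dataset`: list with `samples`
#'   (`n x T x M` array), `y0` (`n x M`, the first time point of each sample),
#'   `times`, `measured`, `seed`.
#' @export
sample_dataset <- function(measurements, n, seed = 1L) {
  stopifnot(inherits(measurements, "measurement_series"), n >= 1)
  Tn <- length(measurements$times); M <- ncol(measurements$mean)
  meas <- measurements$measured
  samples <- with_local_seed(seed, {
    a <- array(rep(measurements$mean, each = n), c(n, Tn, M))
    for (k in meas) {
      mu <- matrix(rep(measurements$mean[, k], each = n), n, Tn)
      sd <- matrix(rep(measurements$std[, k], each = n), n, Tn)
      a[, , k] <- pmax(mu + sd * matrix(stats::rnorm(n * Tn), n, Tn), 0)
    }
    a
  })
  structure(list(samples = samples, y0 = matrix(samples[, 1, ], n, M),
                 times = measurements$times, measured = meas,
                 time_unit = measurements$time_unit, seed = as.integer(seed)),
            class = "crn_dataset")
}

#' Masked mean squared error
#'
#' Mean over times and measured species of the squared difference between a
#' prediction and an observation; unmeasured species contribute nothing.
#'
#' @param predicted a [trajectory()] or a `T x M` matrix.
#' @param observed a `T x M` matrix (or trajectory) on the same time grid.
#' @param measured integer indices of the species entering the loss.
#' @return scalar MSE.
#' @export
mse_loss <- function(predicted, observed, measured) {
  P <- if (inherits(predicted, "trajectory")) predicted$states else as.matrix(predicted)
  O <- if (inherits(observed, "trajectory")) observed$states else as.matrix(observed)
  if (!all(dim(P) == dim(O))) stop("prediction/observation grid mismatch")
  mean((P[, measured, drop = FALSE] - O[, measured, drop = FALSE])^2)
}

#' Training configuration
#'
#' @param n_train,n_val,n_test sample counts for the three splits (defaults
#'   1000/100/100).
#' @param lr AdaBelief learning rate (default 6e-3).
#' @param curriculum fraction of each series (by duration) fitted in the first
#'   training phase (default 0.10); 1.0 collapses training to a single phase.
#' @param steps_per_phase optimizer steps per phase (default 200).
#' @param batch_size series per optimizer step (default 32).
#' @param seed master seed for sampling, batching and initialization streams.
#' @param solver [solver_config()] used during training; looser tolerances
#'   than production solves are appropriate.
#' @param val_every validation cadence in optimizer steps.
#' @param beta1,beta2,eps AdaBelief moment parameters.
#' @param dropout must remain 0: dropout destabilizes the ODE solve (rejected
#'   steps) and is deliberately unsupported.
#' @return object of class `training_config`.
#' @export
training_config <- function(n_train = 1000L, n_val = 100L, n_test = 100L,
                            lr = 6e-3, curriculum = 0.10,
                            steps_per_phase = 200L, batch_size = 32L,
                            seed = 1L,
                            solver = solver_config("dopri5", rtol = 1e-4,
                                                   atol = 1e-7),
                            val_every = 20L, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-16, dropout = 0) {
  if (dropout != 0) stop("dropout is not supported (it destabilizes the ODE solve)")
  stopifnot(curriculum > 0, curriculum <= 1, lr > 0, n_train >= 1,
            batch_size >= 1, steps_per_phase >= 1)
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), lr = lr,
                 curriculum = curriculum,
                 steps_per_phase = as.integer(steps_per_phase),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 solver = solver, val_every = as.integer(val_every),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "training_config")
}

# One AdaBelief update. state: list(m, s, t). Returns list(theta, state).
adabelief_step <- function(theta, grad, state, lr, beta1, beta2, eps) {
  if (is.null(state)) state <- list(m = numeric(length(theta)),
                                    s = numeric(length(theta)), t = 0L)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  diff <- grad - state$m
  state$s <- beta2 * state$s + (1 - beta2) * diff * diff + eps
  mhat <- state$m / (1 - beta1^state$t)
  shat <- state$s / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(shat) + eps)
  list(theta = theta, state = state)
}

# Forward-only MSE of a (possibly corrected) model on a dataset, batched.
predict_dataset_mse <- function(network, dataset, correction = NULL,
                                flow = NULL, config = solver_config(),
                                times_idx = NULL) {
  idx <- if (is.null(times_idx)) seq_along(dataset$times) else times_idx
  meas <- dataset$measured
  n <- dim(dataset$samples)[1]
  obs <- dataset$samples[, idx, meas, drop = FALSE]
  if (!is.null(correction)) {
    return(node_loss_grad(network, correction, dataset$y0,
                          dataset$times[idx], obs, flow = flow,
                          config = config, want_grad = FALSE)$loss)
  }
  rhs <- build_rhs(network)
  if (!is.null(flow)) rhs <- apply_flow(rhs, flow)
  jac <- augmented_jacobian(network, NULL, flow)
  res <- ode_integrate(rhs, dataset$y0, dataset$times[idx][1],
                       dataset$times[idx], config, jac = jac, jac_mean = n > 1)
  pred <- res$states[, , meas, drop = FALSE]
  mean((pred - obs)^2)
}

#' Train the neural correction on noisy measurements
#'
#' Fits the correction parameters so the hybrid model matches sampled
#' measurement series, using AdaBelief on the masked MSE with
#' continuous-adjoint gradients. Training runs in two phases: first on the
#' initial `curriculum` fraction of each series (to avoid poor local minima on
#' oscillating data), then on the full series. The returned parameters are the
#' ones with the best validation MSE seen during training, not the final
#' iterate.
#'
#' @param network the (possibly misspecified) mechanistic model to correct.
#' @param correction a freshly initialized [init_correction()]; its
#'   `measured` indices must match the dataset's.
#' @param data a [measurement_series()] (train/validation splits are sampled
#'   internally with seeds `seed`, `seed + 1`) or a list
#'   `list(train = crn_dataset, val = crn_dataset)`.
#' @param config a [training_config()].
#' @param flow optional [flow_conditions()] if the experiment ran in a CSTR.
#' @param rescale_inputs set the correction's input scale constants to the
#'   per-species maximum of the training means (default `TRUE`).
#' @return list with `correction` (best checkpoint), `report` (a
#'   `loss_report`: data.frame of per-step losses with phase labels plus
#'   attributes), and `val_mse` (best validation MSE).
#' @export
train <- function(network, correction, data, config = training_config(),
                  flow = NULL, rescale_inputs = TRUE) {
  if (inherits(data, "measurement_series")) {
    if (!identical(as.integer(data$measured), correction$measured))
      stop("correction and measurements disagree on the measured species")
    ds_train <- sample_dataset(data, config$n_train, seed = config$seed)
    ds_val <- sample_dataset(data, config$n_val, seed = config$seed + 1L)
    if (rescale_inputs) {
      mu <- data$mean[, data$measured, drop = FALSE]
      correction$x_scale <- pmax(apply(mu, 2, max), 1e-12)
      # output scale: largest observed rate of change per species, so the
      # trainable readout is of order one
      rates <- abs(diff(mu)) / diff(data$times)
      correction$out_scale <- pmax(apply(rates, 2, max), 1e-12)
    }
  } else {
    ds_train <- data$train; ds_val <- data$val
    if (rescale_inputs) {
      mu <- apply(ds_train$samples[, , ds_train$measured, drop = FALSE],
                  c(2, 3), mean)
      correction$x_scale <- pmax(apply(mu, 2, max), 1e-12)
      rates <- abs(diff(mu)) / diff(ds_train$times)
      correction$out_scale <- pmax(apply(rates, 2, max), 1e-12)
    }
  }
  stopifnot(inherits(ds_train, "crn_dataset"))
  meas <- ds_train$measured
  times <- ds_train$times
  n_train <- dim(ds_train$samples)[1]
  Tn <- length(times)

  # curriculum: first fraction of the series by duration, at least 2 points
  t_cut <- times[1] + config$curriculum * (times[Tn] - times[1])
  idx1 <- which(times <= t_cut + 1e-12)
  if (length(idx1) < 2) idx1 <- 1:2
  phases <- if (config$curriculum >= 1) list(full = seq_len(Tn))
            else list(curriculum = idx1, full = seq_len(Tn))

  batch_size <- min(config$batch_size, n_train)
  n_steps_total <- config$steps_per_phase * length(phases)
  batches <- with_local_seed(config$seed + 2L, {
    matrix(sample.int(n_train, n_steps_total * batch_size, replace = TRUE),
           n_steps_total, batch_size)
  })

  theta <- theta_get(correction)
  opt_state <- NULL
  validate <- function(corr_now) {
    predict_dataset_mse(network, ds_val, corr_now, flow, config$solver)
  }
  # baseline: the zero-correction model is a valid checkpoint too
  val0 <- validate(correction)
  best <- list(theta = theta, val = val0, step = 0L)
  rows <- vector("list", n_steps_total)
  step_global <- 0L
  t_start <- Sys.time()
  n_failed <- 0L

  for (ph in seq_along(phases)) {
    idx <- phases[[ph]]
    obs_times <- times[idx]
    for (s in seq_len(config$steps_per_phase)) {
      step_global <- step_global + 1L
      bi <- batches[step_global, ]
      Y0 <- ds_train$y0[bi, , drop = FALSE]
      obs <- ds_train$samples[bi, idx, meas, drop = FALSE]
      corr_now <- theta_set(correction, theta)
      res <- try(node_loss_grad(network, corr_now, Y0, obs_times, obs,
                                flow = flow, config = config$solver),
                 silent = TRUE)
      if (inherits(res, "try-error")) {
        n_failed <- n_failed + 1L
        rows[[step_global]] <- data.frame(
          step = step_global, phase = names(phases)[ph],
          train_mse = NA_real_, val_mse = NA_real_, failed = TRUE)
        next
      }
      upd <- adabelief_step(theta, res$grad_theta, opt_state, config$lr,
                            config$beta1, config$beta2, config$eps)
      theta <- upd$theta; opt_state <- upd$state
      val <- NA_real_
      if (step_global %% config$val_every == 0 ||
          s == config$steps_per_phase) {
        val <- validate(theta_set(correction, theta))
        if (is.finite(val) && val < best$val)
          best <- list(theta = theta, val = val, step = step_global)
      }
      rows[[step_global]] <- data.frame(
        step = step_global, phase = names(phases)[ph],
        train_mse = res$loss, val_mse = val, failed = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "phases") <- names(phases)
  attr(report, "seed") <- config$seed
  attr(report, "wall_time_s") <- as.numeric(Sys.time() - t_start,
                                            units = "secs")
  attr(report, "best_step") <- best$step
  attr(report, "n_failed_steps") <- n_failed
  class(report) <- c("loss_report", "data.frame")
  if (n_failed > 0)
    warning(n_failed, " optimizer step(s) were rejected due to solver failures")
  list(correction = theta_set(correction, best$theta), report = report,
       val_mse = best$val)
}

#' @export
print.loss_report <- function(x, ...) {
  cat("<loss_report> ", nrow(x), " steps, phases: ",
      paste(attr(x, "phases"), collapse = " -> "),
      sprintf("; best val MSE %.3e at step %d; %.1f s\n",
              min(x$val_mse, na.rm = TRUE), attr(x, "best_step"),
              attr(x, "wall_time_s")), sep = "")
  invisible(x)
}
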