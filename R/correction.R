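#' Neural correction term
#'
#' The trainable correction \eqn{f_\theta} added to the mechanistic
#' right-hand side. The architecture is an LSTM cell with a 32-dimensional
#' hidden state followed by a single affine readout of the hidden state to the
#' output dimension; identity activations surround the readout (no extra
#' nonlinearity outside the cell's internal gates). The number of inputs and
#' outputs equals the number of measured species.
#'
#' Evaluation is stateless: the cell's hidden and cell states are
#' zero-initialized at every call, so \eqn{f_\theta} is a memoryless function
#' of the instantaneous state. An adaptive ODE solver chooses its own step
#' sequence (and rejects steps), so a history-dependent right-hand side would
#' not be a well-defined ODE; the network sees the measurements at a single
#' time point. A consequence worth knowing: with zero initial hidden/cell
#' state, the recurrent weight matrix of the cell never enters the forward
#' pass. Those parameters are retained (the parameter count matches the usual
#' LSTM-cell formula) but receive zero gradient.
#'
#' The readout weights and bias are initialized to zero so the initial
#' correction is identically zero and training starts exactly at the
#' mechanistic model. Inputs are divided by per-species scale constants
#' (typically the maximum of the training means) before the cell; the readout
#' is multiplied by fixed per-species output scale constants so that the
#' trainable weights stay of order one while the correction itself lives in
#' concentration per time unit.
#'
#' @param n_io number of measured species (network inputs = outputs).
#' @param hidden_size LSTM hidden-state dimension (default 32).
#' @param seed integer seed; the same seed reproduces the same parameters.
#' @param measured integer indices of the measured species within the full
#'   state vector (defaults to `1:n_io`).
#' @param x_scale per-species input scale constants (length `n_io`).
#' @param out_scale per-species output scale constants (length `n_io`), in
#'   concentration per time unit: the correction returned is
#'   `out_scale * (V h + c0)`. A data-derived value (for example the largest
#'   observed rate of change) keeps the trainable readout of order one, which
#'   conditions the optimization; the default 1 leaves the output unscaled.
#' @return object of class `neural_correction`.
#' @export
init_correction <- function(n_io, hidden_size = 32L, seed = 1L,
                            measured = seq_len(n_io), x_scale = rep(1, n_io),
                            out_scale = rep(1, n_io)) {
  stopifnot(n_io >= 1, hidden_size >= 1, length(measured) == n_io,
            length(x_scale) == n_io, all(x_scale > 0),
            length(out_scale) == n_io, all(out_scale > 0))
  H <- as.integer(hidden_size)
  n <- as.integer(n_io)
  lim <- 1 / sqrt(H)
  draws <- with_local_seed(seed, stats::runif(4 * H * n + 4 * H * H + 4 * H,
                                              -lim, lim))
  W <- matrix(draws[seq_len(4 * H * n)], 4 * H, n)
  U <- matrix(draws[4 * H * n + seq_len(4 * H * H)], 4 * H, H)
  b <- draws[4 * H * n + 4 * H * H + seq_len(4 * H)]
  structure(
    list(n_io = n, hidden = H,
         W = W, U = U, b = b,
         V = matrix(0, n, H), c0 = numeric(n),
         x_scale = as.numeric(x_scale), out_scale = as.numeric(out_scale),
         measured = as.integer(measured), seed = as.integer(seed)),
    class = "neural_correction")
}

# Run code under a temporary RNG state; restores the caller's stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @export
print.neural_correction <- function(x, ...) {
  cat("<neural_correction> LSTM cell ", x$n_io, " -> ", x$hidden,
      " -> affine -> ", x$n_io, " (", n_parameters(x), " parameters, seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Total number of parameters of a correction network
#' @param correction a [init_correction()] object.
#' @return integer count.
#' @export
n_parameters <- function(correction) {
  length(correction$W) + length(correction$U) + length(correction$b) +
    length(correction$V) + length(correction$c0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass (compiled kernel). Y: B x n_io matrix of measured
# concentrations (unscaled). Returns list(out = B x n_io, cache); the cache is
# retained for the backward pass. The test suite checks this against an
# independently hand-rolled R implementation of the cell equations.
correction_forward <- function(corr, Y, want_cache = FALSE) {
  res <- cpp_lstm_forward(Y, corr$W, corr$b, corr$V, corr$c0, corr$x_scale,
                          corr$out_scale, want_cache)
  if (!want_cache) return(res)
  list(out = res$out,
       cache = list(X = res$X, gi = res$gi, gg = res$gg, go = res$go,
                    tc = res$tc, h = res$h))
}

# Backward pass (vector-Jacobian products, compiled). dOut: B x n_io
# cotangent. Returns `gth` (flat parameter gradient in the trainable layout
# W, b, V, c0, summed over the batch) and `dY` (gradient w.r.t. the unscaled
# input).
correction_backward <- function(corr, cache, dOut) {
  cpp_lstm_backward(cache$X, cache$gi, cache$gg, cache$go, cache$tc, cache$h,
                    dOut, corr$W, corr$V, corr$x_scale, corr$out_scale)
}

#' Evaluate the neural correction at one or more states
#'
#' Pure function of the parameters and the instantaneous measured state:
#' repeated calls with the same arguments return identical results.
#'
#' @param correction a [init_correction()] object.
#' @param y numeric vector of length `n_io` (the state restricted to measured
#'   species) or a `B x n_io` matrix of such states.
#' @return contribution in concentration per time unit; same shape as `y`.
#' @export
eval_correction <- function(correction, y) {
  vec <- !is.matrix(y)
  Y <- if (vec) matrix(y, 1) else y
  if (ncol(Y) != correction$n_io)
    stop("state has ", ncol(Y), " species, correction expects ", correction$n_io)
  if (any(!is.finite(Y))) stop("non-finite input to eval_correction")
  out <- correction_forward(correction, Y)$out
  if (vec) drop(out) else out
}

# Jacobian d f_theta / d y (unscaled input) at states Y: array B x n_io x n_io,
# assembled from n_io backward passes with basis cotangents.
correction_input_jacobian <- function(corr, Y) {
  B <- nrow(Y); n <- corr$n_io
  fw <- correction_forward(corr, Y, want_cache = TRUE)
  J <- array(0, c(B, n, n))
  for (m in seq_len(n)) {
    dOut <- matrix(0, B, n)
    dOut[, m] <- 1
    J[, m, ] <- correction_backward(corr, fw$cache, dOut)$dY
  }
  J
}

# --- parameter vector plumbing ---------------------------------------------

#' Get or set the trainable parameter vector of a correction
#'
#' The trainable parameters are the cell input weights `W`, the cell bias
#' `b`, the readout weights `V` and the readout bias `c0`, flattened in that
#' order (column-major). The recurrent weight matrix `U` is excluded: under
#' stateless evaluation (zero initial hidden/cell state) it never enters the
#' forward pass and would receive zero gradient.
#'
#' @param corr a [init_correction()] object.
#' @return `theta_get` returns a numeric vector; `theta_set` the updated
#'   correction.
#' @export
theta_get <- function(corr) {
  c(as.vector(corr$W), corr$b, as.vector(corr$V), corr$c0)
}

#' @rdname theta_get
#' @param theta replacement parameter vector, as laid out by `theta_get`.
#' @export
theta_set <- function(corr, theta) {
  H <- corr$hidden; n <- corr$n_io
  sizes <- c(4 * H * n, 4 * H, n * H, n)
  stopifnot(length(theta) == sum(sizes))
  off <- cumsum(c(0, sizes))
  corr$W <- matrix(theta[(off[1] + 1):off[2]], 4 * H, n)
  corr$b <- theta[(off[2] + 1):off[3]]
  corr$V <- matrix(theta[(off[3] + 1):off[4]], n, H)
  corr$c0 <- theta[(off[4] + 1):off[5]]
  corr
}

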