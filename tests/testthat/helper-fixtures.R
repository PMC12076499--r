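# Shared fixtures and independent oracles used across test files.

# Two-species toy networks
net_first_order <- function(k = 2) {
  crn_network(
    data.frame(index = 1:2, name = c("A", "B"), constant = c(FALSE, FALSE)),
    list(reaction(c(A = 1), c(B = 1), rate_constant = "k", label = "conv")),
    c(k = k))
}

net_autocatalytic <- function(k = 1) {
  crn_network(
    data.frame(index = 1:2, name = c("A", "B"), constant = c(FALSE, FALSE)),
    list(reaction(c(A = 1, B = 1), c(B = 2), rate_constant = "k",
                  label = "auto")),
    c(k = k))
}

net_zero_reactions <- function(M = 3) {
  crn_network(
    data.frame(index = seq_len(M), name = paste0("S", seq_len(M)),
               constant = rep(FALSE, M)),
    list(), c(k = 1))
}

# Literal term-by-term transcription of the seven-species oscillator ODEs,
# independent of the generic builder. Species order:
# 1 piperidine, 2 Fmoc-piperidine, 3 p-nitrophenyl acetate, 4 phenyl acetate,
# 5 N-methylpiperidine (constant), 6 dibenzofulvene, 7 N-acetyl piperidine.
fmoc_rhs_oracle <- function(kappa) {
  function(t, y) {
    v_tr <- kappa["k_tr"] * y[2] * y[5]
    v_ac <- kappa["k_ac"] * y[1] * y[2]
    v_i1 <- kappa["k_inh1"] * y[1] * y[3]
    v_i2 <- kappa["k_inh2"] * y[1] * y[4]
    unname(c(v_tr + v_ac - v_i1 - v_i2,
             -v_tr - v_ac,
             -v_i1,
             -v_i2,
             0,
             v_tr + v_ac,
             v_i1 + v_i2))
  }
}

# Independent (hand-rolled) forward pass of the stateless LSTM cell with
# zero-initialized hidden and cell state, plus affine readout.
lstm_oracle <- function(corr, y) {
  x <- y / corr$x_scale
  H <- corr$hidden
  z <- as.vector(corr$W %*% x + corr$b)
  sig <- function(u) 1 / (1 + exp(-u))
  i_g <- sig(z[1:H])
  g_g <- tanh(z[2 * H + 1:H])
  o_g <- sig(z[3 * H + 1:H])
  cell <- i_g * g_g
  h <- o_g * tanh(cell)
  as.vector(corr$V %*% h + corr$c0)
}

random_nonneg_state <- function(M, scale = 1) {
  stats::runif(M, 0, scale)
}

# Dominant-period estimate via the discrete Fourier transform (independent
# spectral oracle for the peak-based estimator). Uniform grid assumed.
spectral_period <- function(t, x) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:floor(n / 2)]
  freq <- (1:(floor(n / 2) - 1)) / (n * (t[2] - t[1]))
  1 / freq[which.max(sp)]
}
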