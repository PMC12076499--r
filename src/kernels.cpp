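// Hot numerical kernels: batched mass-action right-hand sides, Jacobians and
// transposed-Jacobian products, and the stateless LSTM-cell correction
// (forward and backward). All state matrices are B x M (samples x species).
// These are performance ports of the reference R implementations; the test
// suite checks them against independently hand-rolled R oracles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// rates V (B x R): V(:,j) = k[j] * prod_s Y(:,s)^E(s,j)
static arma::mat rate_matrix(const arma::mat& Y, const arma::vec& k,
                             const arma::mat& E) {
  const arma::uword B = Y.n_rows, R = E.n_cols;
  arma::mat V(B, R);
  for (arma::uword j = 0; j < R; ++j) {
    arma::vec v(B, arma::fill::value(k[j]));
    for (arma::uword s = 0; s < E.n_rows; ++s) {
      const double e = E(s, j);
      if (e == 0.0) continue;
      if (e == 1.0) v %= Y.col(s);
      else if (e == 2.0) v %= arma::square(Y.col(s));
      else v %= arma::pow(Y.col(s), e);
    }
    V.col(j) = v;
  }
  return V;
}

// [[Rcpp::export]]
arma::mat cpp_ma_rhs(const arma::mat& Y, const arma::vec& k,
                     const arma::mat& E, const arma::mat& Seff) {
  return rate_matrix(Y, k, E) * Seff.t();
}

// d v_j / d y_s for one reaction, all samples
static arma::vec rate_deriv(const arma::mat& Y, const arma::vec& k,
                            const arma::mat& E, arma::uword j,
                            arma::uword s) {
  const double e = E(s, j);
  arma::vec dv(Y.n_rows, arma::fill::value(k[j] * e));
  if (e == 2.0) dv %= Y.col(s);
  else if (e != 1.0) dv %= arma::pow(Y.col(s), e - 1.0);
  for (arma::uword s2 = 0; s2 < E.n_rows; ++s2) {
    if (s2 == s) continue;
    const double e2 = E(s2, j);
    if (e2 == 0.0) continue;
    if (e2 == 1.0) dv %= Y.col(s2);
    else if (e2 == 2.0) dv %= arma::square(Y.col(s2));
    else dv %= arma::pow(Y.col(s2), e2);
  }
  return dv;
}

// Jacobian as an R array with dim c(B, M, M): element (b, m, s) = d f_m / d y_s
// [[Rcpp::export]]
NumericVector cpp_ma_jac(const arma::mat& Y, const arma::vec& k,
                         const arma::mat& E, const arma::mat& Seff) {
  const arma::uword B = Y.n_rows, M = Y.n_cols, R = E.n_cols;
  NumericVector J(B * M * M);
  for (arma::uword j = 0; j < R; ++j) {
    for (arma::uword s = 0; s < M; ++s) {
      if (E(s, j) == 0.0) continue;
      const arma::vec dv = rate_deriv(Y, k, E, j, s);
      for (arma::uword m = 0; m < M; ++m) {
        const double smj = Seff(m, j);
        if (smj == 0.0) continue;
        for (arma::uword b = 0; b < B; ++b)
          J[b + B * m + B * M * s] += smj * dv[b];
      }
    }
  }
  J.attr("dim") = IntegerVector::create(B, M, M);
  return J;
}

// J(Y)^T L (B x M) and, when harvest, the per-reaction kappa products
// sum_b (L_b . S[, j]) * v_j(Y_b) / k_j
// [[Rcpp::export]]
List cpp_ma_jtv(const arma::mat& Y, const arma::mat& L, const arma::vec& k,
                const arma::mat& E, const arma::mat& Seff,
                const bool harvest) {
  const arma::uword B = Y.n_rows, M = Y.n_cols, R = E.n_cols;
  arma::mat out(B, M, arma::fill::zeros);
  arma::vec gk(R, arma::fill::zeros);
  for (arma::uword j = 0; j < R; ++j) {
    const arma::vec wj = L * Seff.col(j);
    for (arma::uword s = 0; s < M; ++s) {
      if (E(s, j) == 0.0) continue;
      out.col(s) += rate_deriv(Y, k, E, j, s) % wj;
    }
    if (harvest) {
      arma::vec v(B, arma::fill::ones);
      for (arma::uword s = 0; s < M; ++s) {
        const double e = E(s, j);
        if (e == 0.0) continue;
        if (e == 1.0) v %= Y.col(s);
        else if (e == 2.0) v %= arma::square(Y.col(s));
        else v %= arma::pow(Y.col(s), e);
      }
      gk[j] = arma::dot(wj, v);
    }
  }
  return List::create(_["out"] = out,
                      _["gk"] = NumericVector(gk.begin(), gk.end()));
}

// Stateless LSTM cell + affine readout, batched.
// Y: B x n (unscaled); W: 4H x n; b: 4H; V: n x H; c0: n; xscale: n;
// oscale: n (fixed output scale constants; the correction is
// oscale * (V h + c0), so the trainable readout stays O(1)).
// Gate order along the 4H axis: input, forget, cell candidate, output.
// [[Rcpp::export]]
List cpp_lstm_forward(const arma::mat& Y, const arma::mat& W,
                      const arma::vec& b, const arma::mat& V,
                      const arma::vec& c0, const arma::vec& xscale,
                      const arma::vec& oscale, const bool want_cache) {
  const arma::uword B = Y.n_rows, H = V.n_cols;
  arma::mat X = Y;
  X.each_row() /= xscale.t();
  arma::mat Z = X * W.t();
  Z.each_row() += b.t();
  arma::mat gi = 1.0 / (1.0 + arma::exp(-Z.cols(0, H - 1)));
  arma::mat gg = arma::tanh(Z.cols(2 * H, 3 * H - 1));
  arma::mat go = 1.0 / (1.0 + arma::exp(-Z.cols(3 * H, 4 * H - 1)));
  arma::mat tc = arma::tanh(gi % gg);        // tanh(c), c = i*g (c0 = 0)
  arma::mat h = go % tc;
  arma::mat out = h * V.t();
  out.each_row() += c0.t();
  out.each_row() %= oscale.t();
  if (!want_cache) return List::create(_["out"] = out);
  return List::create(_["out"] = out,
                      _["X"] = X, _["gi"] = gi, _["gg"] = gg,
                      _["go"] = go, _["tc"] = tc, _["h"] = h);
}

// Backward pass: parameter gradients summed over the batch (flattened in the
// trainable layout W, b, V, c0) and the VJP w.r.t. the unscaled input.
// [[Rcpp::export]]
List cpp_lstm_backward(const arma::mat& X, const arma::mat& gi,
                       const arma::mat& gg, const arma::mat& go,
                       const arma::mat& tc, const arma::mat& h,
                       const arma::mat& dOut_raw, const arma::mat& W,
                       const arma::mat& V, const arma::vec& xscale,
                       const arma::vec& oscale) {
  const arma::uword B = X.n_rows, n = X.n_cols, H = V.n_cols;
  arma::mat dOut = dOut_raw;
  dOut.each_row() %= oscale.t();
  arma::mat dV = dOut.t() * h;                       // n x H
  arma::rowvec dc0 = arma::sum(dOut, 0);
  arma::mat dh = dOut * V;                           // B x H
  arma::mat dgo = dh % tc;
  arma::mat dcell = dh % go % (1.0 - arma::square(tc));
  arma::mat dzi = (dcell % gg) % gi % (1.0 - gi);
  arma::mat dzg = (dcell % gi) % (1.0 - arma::square(gg));
  arma::mat dzo = dgo % go % (1.0 - go);
  arma::mat dZ(B, 4 * H, arma::fill::zeros);
  dZ.cols(0, H - 1) = dzi;
  dZ.cols(2 * H, 3 * H - 1) = dzg;
  dZ.cols(3 * H, 4 * H - 1) = dzo;
  arma::mat dW = dZ.t() * X;                         // 4H x n
  arma::rowvec db = arma::sum(dZ, 0);
  arma::mat dY = dZ * W;                             // B x n (w.r.t. scaled X)
  dY.each_row() /= xscale.t();
  // flat gradient in the trainable layout: W (col-major), b, V (col-major), c0
  const arma::uword nth = 4 * H * n + 4 * H + n * H + n;
  arma::vec gth(nth);
  arma::uword off = 0;
  std::memcpy(gth.memptr() + off, dW.memptr(), sizeof(double) * 4 * H * n);
  off += 4 * H * n;
  for (arma::uword i = 0; i < 4 * H; ++i) gth[off + i] = db[i];
  off += 4 * H;
  std::memcpy(gth.memptr() + off, dV.memptr(), sizeof(double) * n * H);
  off += n * H;
  for (arma::uword i = 0; i < n; ++i) gth[off + i] = dc0[i];
  return List::create(_["gth"] = NumericVector(gth.begin(), gth.end()),
                      _["dY"] = dY);
}
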