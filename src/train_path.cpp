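// Compiled fast path for training: forward solve of the augmented
// (mass-action + LSTM correction [+ CSTR flow]) system with the explicit
// Dormand-Prince 5(4) pair, followed by the continuous-adjoint backward sweep
// with Runge-Kutta stage quadrature of the parameter gradient. Semantically
// identical to the R implementation in R/adjoint.R (method = "dopri5"); the
// test suite checks the two paths against each other.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct MassAction {
  arma::vec k;
  arma::mat E;      // M x R exponents
  arma::mat Seff;   // M x R effective stoichiometry
};

struct Lstm {
  arma::mat W;      // 4H x n
  arma::vec b;      // 4H
  arma::mat V;      // n x H
  arma::vec c0;     // n
  arma::vec xscale; // n
  arma::vec oscale; // n (fixed output scale)
};

struct Flow {
  double D = 0.0;
  arma::vec y_in;           // M
  arma::uvec open;          // indices of non-constant species
};

struct LstmCache {
  arma::mat X, gi, gg, go, tc, h;
};

arma::mat ma_rhs(const MassAction& ma, const arma::mat& Y) {
  const arma::uword B = Y.n_rows, R = ma.E.n_cols;
  arma::mat V(B, R);
  for (arma::uword j = 0; j < R; ++j) {
    arma::vec v(B, arma::fill::value(ma.k[j]));
    for (arma::uword s = 0; s < ma.E.n_rows; ++s) {
      const double e = ma.E(s, j);
      if (e == 0.0) continue;
      if (e == 1.0) v %= Y.col(s);
      else if (e == 2.0) v %= arma::square(Y.col(s));
      else v %= arma::pow(Y.col(s), e);
    }
    V.col(j) = v;
  }
  return V * ma.Seff.t();
}

arma::vec ma_rate_deriv(const MassAction& ma, const arma::mat& Y,
                        arma::uword j, arma::uword s) {
  const double e = ma.E(s, j);
  arma::vec dv(Y.n_rows, arma::fill::value(ma.k[j] * e));
  if (e == 2.0) dv %= Y.col(s);
  else if (e != 1.0) dv %= arma::pow(Y.col(s), e - 1.0);
  for (arma::uword s2 = 0; s2 < ma.E.n_rows; ++s2) {
    if (s2 == s) continue;
    const double e2 = ma.E(s2, j);
    if (e2 == 0.0) continue;
    if (e2 == 1.0) dv %= Y.col(s2);
    else if (e2 == 2.0) dv %= arma::square(Y.col(s2));
    else dv %= arma::pow(Y.col(s2), e2);
  }
  return dv;
}

arma::mat lstm_forward(const Lstm& nn, const arma::mat& Ym, LstmCache* cache) {
  const arma::uword H = nn.V.n_cols;
  arma::mat X = Ym;
  X.each_row() /= nn.xscale.t();
  arma::mat Z = X * nn.W.t();
  Z.each_row() += nn.b.t();
  arma::mat gi = 1.0 / (1.0 + arma::exp(-Z.cols(0, H - 1)));
  arma::mat gg = arma::tanh(Z.cols(2 * H, 3 * H - 1));
  arma::mat go = 1.0 / (1.0 + arma::exp(-Z.cols(3 * H, 4 * H - 1)));
  arma::mat tc = arma::tanh(gi % gg);
  arma::mat h = go % tc;
  arma::mat out = h * nn.V.t();
  out.each_row() += nn.c0.t();
  out.each_row() %= nn.oscale.t();
  if (cache) {
    cache->X = std::move(X); cache->gi = std::move(gi);
    cache->gg = std::move(gg); cache->go = std::move(go);
    cache->tc = std::move(tc); cache->h = std::move(h);
  }
  return out;
}

// backward pass; accumulates flat theta gradient (layout W, b, V, c0) into
// gth with weight w, returns dY (w.r.t. unscaled input)
arma::mat lstm_backward(const Lstm& nn, const LstmCache& c,
                        const arma::mat& dOut_raw, double w, arma::vec* gth) {
  const arma::uword B = c.X.n_rows, n = c.X.n_cols, H = nn.V.n_cols;
  arma::mat dOut = dOut_raw;
  dOut.each_row() %= nn.oscale.t();
  arma::mat dh = dOut * nn.V;
  arma::mat dgo = dh % c.tc;
  arma::mat dcell = dh % c.go % (1.0 - arma::square(c.tc));
  arma::mat dzi = (dcell % c.gg) % c.gi % (1.0 - c.gi);
  arma::mat dzg = (dcell % c.gi) % (1.0 - arma::square(c.gg));
  arma::mat dzo = dgo % c.go % (1.0 - c.go);
  arma::mat dZ(B, 4 * H, arma::fill::zeros);
  dZ.cols(0, H - 1) = dzi;
  dZ.cols(2 * H, 3 * H - 1) = dzg;
  dZ.cols(3 * H, 4 * H - 1) = dzo;
  arma::mat dY = dZ * nn.W;
  dY.each_row() /= nn.xscale.t();
  if (gth) {
    arma::mat dW = dZ.t() * c.X;
    arma::rowvec db = arma::sum(dZ, 0);
    arma::mat dV = dOut.t() * c.h;
    arma::rowvec dc0 = arma::sum(dOut, 0);
    arma::uword off = 0;
    for (arma::uword i = 0; i < 4 * H * n; ++i) (*gth)[off + i] += w * dW[i];
    off += 4 * H * n;
    for (arma::uword i = 0; i < 4 * H; ++i) (*gth)[off + i] += w * db[i];
    off += 4 * H;
    for (arma::uword i = 0; i < n * H; ++i) (*gth)[off + i] += w * dV[i];
    off += n * H;
    for (arma::uword i = 0; i < n; ++i) (*gth)[off + i] += w * dc0[i];
  }
  return dY;
}

struct Model {
  MassAction ma;
  Lstm nn;
  Flow flow;
  arma::uvec meas;     // 0-based measured species indices
  arma::uword M;
};

// augmented rhs: mass action + flow + scattered correction
arma::mat aug_rhs(const Model& md, const arma::mat& Y) {
  arma::mat dy = ma_rhs(md.ma, Y);
  if (md.flow.D > 0) {
    for (arma::uword ii = 0; ii < md.flow.open.n_elem; ++ii) {
      const arma::uword s = md.flow.open[ii];
      dy.col(s) += md.flow.D * (md.flow.y_in[s] - Y.col(s));
    }
  }
  arma::mat out = lstm_forward(md.nn, Y.cols(md.meas), nullptr);
  for (arma::uword ii = 0; ii < md.meas.n_elem; ++ii)
    dy.col(md.meas[ii]) += out.col(ii);
  return dy;
}

// adjoint rhs J^T L (in tau); optionally harvest parameter VJPs
arma::mat adj_rhs(const Model& md, const arma::mat& Y, const arma::mat& L,
                  double w, arma::vec* gth, arma::vec* gk) {
  const arma::uword B = Y.n_rows, R = md.ma.E.n_cols;
  arma::mat out(B, md.M, arma::fill::zeros);
  for (arma::uword j = 0; j < R; ++j) {
    const arma::vec wj = L * md.ma.Seff.col(j);
    for (arma::uword s = 0; s < md.M; ++s) {
      if (md.ma.E(s, j) == 0.0) continue;
      out.col(s) += ma_rate_deriv(md.ma, Y, j, s) % wj;
    }
    if (gk) {
      arma::vec v(B, arma::fill::ones);
      for (arma::uword s = 0; s < md.M; ++s) {
        const double e = md.ma.E(s, j);
        if (e == 0.0) continue;
        if (e == 1.0) v %= Y.col(s);
        else if (e == 2.0) v %= arma::square(Y.col(s));
        else v %= arma::pow(Y.col(s), e);
      }
      (*gk)[j] += w * arma::dot(wj, v);
    }
  }
  if (md.flow.D > 0)
    for (arma::uword ii = 0; ii < md.flow.open.n_elem; ++ii) {
      const arma::uword s = md.flow.open[ii];
      out.col(s) -= md.flow.D * L.col(s);
    }
  LstmCache cache;
  lstm_forward(md.nn, Y.cols(md.meas), &cache);
  arma::mat dY = lstm_backward(md.nn, cache, L.cols(md.meas), w, gth);
  for (arma::uword ii = 0; ii < md.meas.n_elem; ++ii)
    out.col(md.meas[ii]) += dY.col(ii);
  return out;
}

struct Dopri5 {
  arma::mat A;
  arma::vec b, berr, c;
  Dopri5() {
    A.zeros(7, 7);
    A(1, 0) = 1.0 / 5;
    A(2, 0) = 3.0 / 40; A(2, 1) = 9.0 / 40;
    A(3, 0) = 44.0 / 45; A(3, 1) = -56.0 / 15; A(3, 2) = 32.0 / 9;
    A(4, 0) = 19372.0 / 6561; A(4, 1) = -25360.0 / 2187;
    A(4, 2) = 64448.0 / 6561; A(4, 3) = -212.0 / 729;
    A(5, 0) = 9017.0 / 3168; A(5, 1) = -355.0 / 33;
    A(5, 2) = 46732.0 / 5247; A(5, 3) = 49.0 / 176;
    A(5, 4) = -5103.0 / 18656;
    A(6, 0) = 35.0 / 384; A(6, 2) = 500.0 / 1113; A(6, 3) = 125.0 / 192;
    A(6, 4) = -2187.0 / 6784; A(6, 5) = 11.0 / 84;
    b = A.row(6).t();
    arma::vec bh = {5179.0 / 57600, 0.0, 7571.0 / 16695, 393.0 / 640,
                    -92097.0 / 339200, 187.0 / 2100, 1.0 / 40};
    berr = b - bh;
    c = arma::sum(A, 1);
  }
};

double err_norm(const arma::mat& E, const arma::mat& Y0, const arma::mat& Y1,
                double rtol, double atol) {
  const arma::mat sc = atol + rtol * arma::max(arma::abs(Y0), arma::abs(Y1));
  return std::sqrt(arma::accu(arma::square(E / sc)) / E.n_elem);
}

struct DenseMesh {
  std::vector<double> t;
  std::vector<arma::mat> y, f;
  arma::mat interp(double tq) const {
    const arma::uword n = t.size();
    if (tq <= t.front()) return y.front();
    if (tq >= t.back()) return y.back();
    arma::uword lo = std::upper_bound(t.begin(), t.end(), tq) - t.begin() - 1;
    const double h = t[lo + 1] - t[lo];
    const double s = (tq - t[lo]) / h;
    const double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
    const double h10 = s * (1 - s) * (1 - s);
    const double h01 = s * s * (3 - 2 * s);
    const double h11 = s * s * (s - 1);
    return h00 * y[lo] + (h10 * h) * f[lo] + h01 * y[lo + 1] +
           (h11 * h) * f[lo + 1];
  }
};

}  // namespace

// Forward solve + loss [+ continuous-adjoint gradient] of the nODE MSE fit.
// obs: B x T x K array (K = number of measured species) as an R array.
// Returns list(loss, pred (B x T x M), grad_theta, grad_kappa_per_reaction).
// [[Rcpp::export]]
List cpp_node_loss_grad(const arma::mat& Y0, const arma::vec& obs_times,
                        const NumericVector& obs, const arma::vec& k,
                        const arma::mat& E, const arma::mat& Seff,
                        const arma::mat& W, const arma::vec& b,
                        const arma::mat& V, const arma::vec& c0,
                        const arma::vec& xscale, const arma::vec& oscale,
                        const arma::uvec& meas1,
                        const double flowD, const arma::vec& flow_yin,
                        const arma::uvec& open1, const double rtol,
                        const double atol, const int max_steps,
                        const bool want_grad) {
  Model md;
  md.ma = MassAction{k, E, Seff};
  md.nn = Lstm{W, b, V, c0, xscale, oscale};
  md.flow = Flow{flowD,
                 flowD > 0 ? flow_yin : arma::vec(Y0.n_cols,
                                                  arma::fill::zeros),
                 open1 - 1};
  md.meas = meas1 - 1;  // to 0-based
  md.M = Y0.n_cols;
  const arma::uword B = Y0.n_rows, M = md.M, Tn = obs_times.n_elem,
                    K = md.meas.n_elem;
  const Dopri5 tb;
  const double t_end = obs_times[Tn - 1];

  // ---- forward pass -------------------------------------------------------
  DenseMesh mesh;
  arma::cube pred(B, Tn, M);
  double t = obs_times[0];
  arma::mat Y = Y0;
  arma::mat f_now = aug_rhs(md, Y);
  if (!f_now.is_finite()) stop("non-finite RHS at the initial state");
  for (arma::uword m = 0; m < M; ++m) pred.slice(m).col(0) = Y.col(m);
  arma::uword isave = 1;
  mesh.t.push_back(t); mesh.y.push_back(Y); mesh.f.push_back(f_now);

  double h;
  {
    const arma::mat sc = atol + rtol * arma::abs(Y);
    const double d0 = std::sqrt(arma::accu(arma::square(Y / sc)) / Y.n_elem);
    const double d1 =
        std::sqrt(arma::accu(arma::square(f_now / sc)) / Y.n_elem);
    h = (d1 > 1e-10) ? 0.01 * d0 / d1 : 1e-6 * std::max(1.0, t_end - t);
    h = std::min(h, t_end - t);
    if (h <= 0) h = 1e-6;
  }

  std::vector<arma::mat> Kst(7);
  int n_steps = 0;
  while (t < t_end - 1e-14 * std::max(1.0, std::fabs(t_end))) {
    if (++n_steps > max_steps)
      stop("forward solve exceeded max_steps at t = %f", t);
    h = std::min(h, t_end - t);
    if (isave < Tn && t + h > obs_times[isave] - 1e-14)
      h = obs_times[isave] - t;
    bool failed = false;
    Kst[0] = f_now;
    for (arma::uword i = 1; i < 7; ++i) {
      arma::mat acc = Y;
      for (arma::uword j = 0; j < i; ++j)
        if (tb.A(i, j) != 0.0) acc += (h * tb.A(i, j)) * Kst[j];
      Kst[i] = aug_rhs(md, acc);
      if (!Kst[i].is_finite()) { failed = true; break; }
    }
    if (!failed) {
      arma::mat Y1 = Y;
      for (arma::uword i = 0; i < 7; ++i)
        if (tb.b[i] != 0.0) Y1 += (h * tb.b[i]) * Kst[i];
      arma::mat Eac(B, M, arma::fill::zeros);
      for (arma::uword i = 0; i < 7; ++i)
        if (tb.berr[i] != 0.0) Eac += (h * tb.berr[i]) * Kst[i];
      const double err = err_norm(Eac, Y, Y1, rtol, atol);
      if (std::isfinite(err) && err <= 1.0) {
        t += h;
        Y = Y1;
        f_now = Kst[6];  // FSAL
        while (isave < Tn &&
               obs_times[isave] <= t + 1e-14 * std::max(1.0, std::fabs(t))) {
          for (arma::uword m = 0; m < M; ++m)
            pred.slice(m).col(isave) = Y.col(m);
          ++isave;
        }
        mesh.t.push_back(t); mesh.y.push_back(Y); mesh.f.push_back(f_now);
        h *= std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
        continue;
      }
      h *= std::min(1.0, std::max(0.1, 0.9 * std::pow(
          std::isfinite(err) ? err : 10.0, -0.2)));
    } else {
      h /= 2;
    }
    if (h < 1e-14 * std::max(1.0, std::fabs(t_end)))
      stop("forward step size underflow at t = %f", t);
  }

  // ---- loss ---------------------------------------------------------------
  // obs index (b, i, kk) = b + B*i + B*Tn*kk
  double loss = 0.0;
  arma::cube resid(B, Tn, K);
  for (arma::uword kk = 0; kk < K; ++kk)
    for (arma::uword i = 0; i < Tn; ++i)
      for (arma::uword bq = 0; bq < B; ++bq) {
        const double r = pred(bq, i, md.meas[kk]) - obs[bq + B * i + B * Tn * kk];
        resid(bq, i, kk) = r;
        loss += r * r;
      }
  loss /= (double)(B * Tn * K);

  List out = List::create(_["loss"] = loss, _["pred"] = pred);
  if (!want_grad) return out;

  // ---- adjoint sweep ------------------------------------------------------
  const arma::uword nth = W.n_elem + b.n_elem + V.n_elem + c0.n_elem;
  arma::vec gth(nth, arma::fill::zeros);
  arma::vec gk(k.n_elem, arma::fill::zeros);
  arma::mat L(B, M, arma::fill::zeros);
  double h_carry = -1.0;

  for (arma::uword i = Tn - 1; i >= 1; --i) {
    for (arma::uword kk = 0; kk < K; ++kk)
      L.col(md.meas[kk]) += resid.slice(kk).col(i);
    const double t_hi = obs_times[i], t_lo = obs_times[i - 1];
    const double Delta = t_hi - t_lo;
    double tau = 0.0;
    std::vector<arma::mat> Ka(7);
    std::vector<arma::vec> Pth(7, arma::vec(nth, arma::fill::zeros));
    std::vector<arma::vec> Pk(7, arma::vec(k.n_elem, arma::fill::zeros));
    // stage-1 value and harvest at the (jumped) interval start
    arma::vec gth1(nth, arma::fill::zeros), gk1(k.n_elem, arma::fill::zeros);
    arma::mat fL = adj_rhs(md, mesh.interp(t_hi), L, 1.0, &gth1, &gk1);
    double ha;
    if (h_carry > 0) {
      ha = h_carry;
    } else {
      const arma::mat sc = atol + rtol * arma::abs(L);
      const double d0 = std::sqrt(arma::accu(arma::square(L / sc)) / L.n_elem);
      const double d1 =
          std::sqrt(arma::accu(arma::square(fL / sc)) / L.n_elem);
      ha = (d1 > 1e-10) ? std::min(0.01 * std::max(d0, 1.0) / d1, Delta)
                        : Delta / 8;
      if (ha <= 0 || !std::isfinite(ha)) ha = Delta / 8;
    }
    int na = 0;
    while (tau < Delta - 1e-14 * std::max(1.0, Delta)) {
      if (++na > max_steps) stop("adjoint sweep exceeded max_steps");
      ha = std::min(ha, Delta - tau);
      bool failed = false;
      Ka[0] = fL;
      Pth[0] = gth1; Pk[0] = gk1;
      for (arma::uword s = 1; s < 7; ++s) {
        arma::mat acc = L;
        for (arma::uword j = 0; j < s; ++j)
          if (tb.A(s, j) != 0.0) acc += (ha * tb.A(s, j)) * Ka[j];
        const double ts = tau + tb.c[s] * ha;
        const bool harvest = (tb.b[s] != 0.0) || s == 6;
        if (harvest) { Pth[s].zeros(); Pk[s].zeros(); }
        Ka[s] = adj_rhs(md, mesh.interp(t_hi - ts), acc, 1.0,
                        harvest ? &Pth[s] : nullptr,
                        harvest ? &Pk[s] : nullptr);
        if (!Ka[s].is_finite()) { failed = true; break; }
      }
      if (!failed) {
        arma::mat L1 = L;
        for (arma::uword s = 0; s < 7; ++s)
          if (tb.b[s] != 0.0) L1 += (ha * tb.b[s]) * Ka[s];
        arma::mat Eac(B, M, arma::fill::zeros);
        for (arma::uword s = 0; s < 7; ++s)
          if (tb.berr[s] != 0.0) Eac += (ha * tb.berr[s]) * Ka[s];
        const double err = err_norm(Eac, L, L1, rtol, atol);
        if (std::isfinite(err) && err <= 1.0) {
          for (arma::uword s = 0; s < 7; ++s)
            if (tb.b[s] != 0.0) {
              gth += (ha * tb.b[s]) * Pth[s];
              gk += (ha * tb.b[s]) * Pk[s];
            }
          tau += ha;
          L = L1;
          fL = Ka[6];
          gth1 = Pth[6]; gk1 = Pk[6];  // FSAL harvest carry
          ha *= std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
          continue;
        }
        ha *= std::min(1.0, std::max(0.1, 0.9 * std::pow(
            std::isfinite(err) ? err : 10.0, -0.2)));
      } else {
        ha /= 2;
      }
      if (ha < 1e-14 * std::max(1.0, Delta))
        stop("adjoint step size underflow");
    }
    h_carry = ha;
  }
  const double dL_scale = 2.0 / (double)(B * Tn * K);
  const arma::vec gts = dL_scale * gth, gks = dL_scale * gk;
  out["grad_theta"] = NumericVector(gts.begin(), gts.end());
  out["grad_kappa"] = NumericVector(gks.begin(), gks.end());
  return out;
}
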