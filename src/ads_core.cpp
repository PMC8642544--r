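// Forward-Euler cores for the rate (teacher) network and the spiking ADS
// network.  Semantics of every update are mirrored 1:1 by the exported R
// primitives (rnn_step, lif_step, synapse_step, filter_spikes); the tests
// assert bit-level equivalence between the two paths on small networks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Simulate the tanh rate network:
//   tau_j x_j' = -x_j + (F c)_j + (Omega tanh(x))_j + b_j,  y = D x
// C is d1 x T; returns states X (N x T, state after each step) and Y (d2 x T).
// [[Rcpp::export]]
List cpp_simulate_rnn(const arma::vec& tau, const arma::mat& F,
                      const arma::mat& Omega, const arma::vec& b,
                      const arma::mat& D, const arma::mat& C,
                      const arma::vec& x0, double dt, double bound) {
  const arma::uword N = tau.n_elem, T = C.n_cols;
  arma::vec a = dt / tau;
  arma::vec x = x0;
  arma::mat X(N, T), Y(D.n_rows, T);
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec drive = -x + F * C.col(t) + Omega * arma::tanh(x) + b;
    x += a % drive;
    if (!x.is_finite() || arma::abs(x).max() > bound) {
      stop("rate network diverged at step %d (|x| above %g)", (int)(t + 1), bound);
    }
    X.col(t) = x;
    Y.col(t) = D * x;
  }
  return List::create(_["X"] = X, _["Y"] = Y);
}

// Batched loss + gradients for BPTT through the Euler-discretised rate
// network.  C: cube (d1, B, T); Ytar: cube (d2, B, T).  Loss is the mean
// squared error over all (output, step, sample) entries.  Gradients are
// returned for tau, F, Omega, b (D is fixed, matching the stated set of
// trainable parameters).
// [[Rcpp::export]]
List cpp_rnn_loss_grad(const arma::vec& tau, const arma::mat& F,
                       const arma::mat& Omega, const arma::vec& b,
                       const arma::mat& D, const arma::cube& C,
                       const arma::cube& Ytar, double dt) {
  const arma::uword N = tau.n_elem, B = C.n_cols, T = C.n_slices;
  const arma::uword d2 = D.n_rows;
  arma::vec a = dt / tau;

  // forward, storing states and pre-leak drives
  arma::cube X(N, B, T), U(N, B, T);
  arma::mat x(N, B, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    arma::mat drive = -x + F * C.slice(t) + Omega * arma::tanh(x) + b * arma::ones<arma::rowvec>(B);
    U.slice(t) = drive;
    x += drive.each_col() % a;
    X.slice(t) = x;
  }

  const double denom = (double)(B * T * d2);
  double loss = 0.0;
  arma::mat g(N, B, arma::fill::zeros);
  arma::mat dF(arma::size(F), arma::fill::zeros);
  arma::mat dOmega(arma::size(Omega), arma::fill::zeros);
  arma::vec db(N, arma::fill::zeros), da(N, arma::fill::zeros);

  for (arma::uword tt = T; tt-- > 0;) {
    arma::mat xt = X.slice(tt);
    arma::mat dy = D * xt - Ytar.slice(tt);
    loss += arma::accu(arma::square(dy));
    g += D.t() * (2.0 / denom) * dy;
    // x_t = x_{t-1} + a .* U_t,  U_t = -x_{t-1} + F c_t + Omega tanh(x_{t-1}) + b
    arma::mat ag = g.each_col() % a;
    arma::mat xprev = (tt == 0) ? arma::mat(N, B, arma::fill::zeros)
                                : arma::mat(X.slice(tt - 1));
    arma::mat phi = arma::tanh(xprev);
    dOmega += ag * phi.t();
    dF += ag * C.slice(tt).t();
    db += arma::sum(ag, 1);
    da += arma::sum(g % U.slice(tt), 1);
    g = g - ag + (Omega.t() * ag) % (1.0 - arma::square(phi));
  }
  arma::vec dtau = da % (-dt / arma::square(tau));
  return List::create(_["loss"] = loss / denom, _["dF"] = dF,
                      _["dOmega"] = dOmega, _["db"] = db, _["dtau"] = dtau);
}

// Spiking ADS simulation (optionally learning Omega_s online).
//
// Per step t (1-based on the R side):
//   I_fast <- I_fast (1 - dt/tau_fast) + (-Omega_f) o_{t-1}
//   I_slow <- I_slow (1 - dt/tau_slow) +   Omega_s  o_{t-1}
//   r      <- r (1 - dt/tau_slow) + o_{t-1}
//   xt     <- F r;  e <- xhat_t - xt (zero without a teacher trajectory)
//   V      <- V + dt/tau_mem (V_rest - V + W_in c_t + I_fast + I_slow + k F'e)
//             + noise_t            (noise pre-scaled, added to V directly)
//   silenced neurons clamped to V_reset; o <- V > V_thresh; V[o] <- V_reset
//   if learning: Omega_s <- Omega_s + eta (F'e) r'
//
// W_fast is passed already negated is NOT done: Omega_f enters with its
// negative sign here, matching the membrane equation.
// [[Rcpp::export]]
List cpp_simulate_ads(const arma::mat& W_in, const arma::mat& Omega_f,
                      arma::mat Omega_s, const arma::mat& F,
                      const arma::mat& W_out, const arma::vec& tau_mem,
                      const arma::vec& v_thresh, const arma::vec& v_rest,
                      double v_reset, const arma::vec& tau_fast,
                      const arma::vec& tau_slow, double dt,
                      const arma::mat& C, const arma::mat& Xhat,
                      double k, double eta, const arma::mat& noise,
                      const arma::ivec& silence_mask, int sil_on, int sil_off,
                      bool learn, bool return_raster) {
  const arma::uword N = tau_mem.n_elem, T = C.n_cols, Nhat = F.n_rows;
  const bool have_xhat = Xhat.n_cols == T;
  const bool have_noise = noise.n_cols == T;
  const bool have_sil = silence_mask.n_elem == N && sil_off > sil_on;

  arma::vec decay_f = 1.0 - dt / tau_fast;
  arma::vec decay_s = 1.0 - dt / tau_slow;
  arma::vec adt = dt / tau_mem;

  arma::vec V = v_rest;
  arma::vec I_fast(N, arma::fill::zeros), I_slow(N, arma::fill::zeros);
  arma::vec r(N, arma::fill::zeros);
  arma::vec o_prev(N, arma::fill::zeros);

  arma::mat Xt(Nhat, T), Y(W_out.n_rows, T);
  arma::umat raster;
  if (return_raster) raster.zeros(N, T);
  double sse = 0.0;

  arma::uvec sil_idx;
  if (have_sil) sil_idx = arma::find(silence_mask != 0);

  for (arma::uword t = 0; t < T; ++t) {
    I_fast = I_fast % decay_f + (-(Omega_f * o_prev));
    I_slow = I_slow % decay_s + Omega_s * o_prev;
    r = r % decay_s + o_prev;
    arma::vec xt = F * r;
    arma::vec e(Nhat, arma::fill::zeros);
    if (have_xhat) e = Xhat.col(t) - xt;
    arma::vec Fe = F.t() * e;
    arma::vec I_tot = W_in * C.col(t) + I_fast + I_slow + k * Fe;
    V += adt % (v_rest - V + I_tot);
    if (have_noise) V += noise.col(t);
    const bool sil_now = have_sil && (int)t >= sil_on && (int)t < sil_off;
    if (sil_now) V.elem(sil_idx).fill(v_reset);
    if (!V.is_finite()) {
      arma::uvec bad = arma::find_nonfinite(V);
      stop("non-finite membrane potential in neuron %d at step %d",
           (int)bad(0) + 1, (int)t + 1);
    }
    arma::uvec sp = arma::find(V > v_thresh);
    o_prev.zeros();
    if (sp.n_elem > 0) {
      o_prev.elem(sp).ones();
      V.elem(sp).fill(v_reset);
      if (return_raster) for (arma::uword j = 0; j < sp.n_elem; ++j) raster(sp(j), t) = 1u;
    }
    if (learn && have_xhat) Omega_s += eta * (Fe * r.t());
    Xt.col(t) = xt;
    Y.col(t) = W_out * xt;
    if (have_xhat) sse += arma::accu(arma::square(e));
  }

  List out = List::create(
      _["Xtilde"] = Xt, _["Y"] = Y, _["Omega_s"] = Omega_s,
      _["mse"] = have_xhat ? sse / (double)(Nhat * T) : NA_REAL);
  if (return_raster) out["raster"] = raster;
  return out;
}
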