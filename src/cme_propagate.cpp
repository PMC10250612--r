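#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// y += (A v) / lam, A in compressed sparse column form
static void csc_axpy(const int n, const IntegerVector &Ap,
                     const IntegerVector &Ai, const NumericVector &Ax,
                     const double *v, double *y, const double inv_lam) {
  for (int j = 0; j < n; ++j) {
    const double vj = v[j];
    if (vj == 0.0) continue;
    const double c = vj * inv_lam;
    for (int ptr = Ap[j]; ptr < Ap[j + 1]; ++ptr) y[Ai[ptr]] += Ax[ptr] * c;
  }
}

// Poisson(q) weights over k = 0..kmax, built outward from the mode so that
// large q never underflows; renormalised to sum to one.
static std::vector<double> poisson_weights(const double q) {
  const int kmode = (int)std::floor(q);
  int kmax = (int)std::ceil(q + 8.5 * std::sqrt(q + 1.0)) + 20;
  std::vector<double> w(kmax + 1, 0.0);
  w[kmode] = 1.0;
  for (int k = kmode + 1; k <= kmax; ++k) {
    w[k] = w[k - 1] * q / k;
    if (w[k] < 1e-18) { kmax = k; break; }
  }
  for (int k = kmode - 1; k >= 0; --k) {
    w[k] = w[k + 1] * (k + 1) / q;
    if (w[k] < 1e-18) break;
  }
  double s = 0.0;
  for (size_t k = 0; k < w.size(); ++k) s += w[k];
  for (size_t k = 0; k < w.size(); ++k) w[k] /= s;
  w.resize(kmax + 1);
  return w;
}

// Propagate the stacked vector [p, s_1, ..., s_d] of the forward sensitivity
// system dv/dt = B v, with B block lower triangular (diagonal blocks the CME
// generator A, sub-diagonal blocks dA_l), across one time-homogeneous
// interval of length dt, by uniformisation: exp(Bt) = e^{-lam t} sum_k
// (lam t)^k/k! (I + B/lam)^k.  A substochastic generator keeps I + A/lam
// non-negative; sensitivity blocks ride along in the same series.  q_max
// bounds the Poisson rate per sub-step (intermediate terms in the sensitivity
// blocks grow linearly in k, so sensitivity solves use modest sub-steps).
static void propagate_interval(const int n, const int d,
                               const IntegerVector &Ap, const IntegerVector &Ai,
                               const NumericVector &Ax, const List &dA,
                               std::vector<double> &v, const double dt,
                               const double lam, const double q_max) {
  if (dt <= 0.0 || lam <= 0.0) return;
  const int nsub = std::max(1, (int)std::ceil(lam * dt / q_max));
  const double q = lam * dt / nsub;
  const double inv_lam = 1.0 / lam;
  const int nb = n * (d + 1);
  std::vector<double> cur(nb), nxt(nb), acc(nb);
  const std::vector<double> w = poisson_weights(q);
  for (int sub = 0; sub < nsub; ++sub) {
    cur = v;
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int i = 0; i < nb; ++i) acc[i] = w[0] * cur[i];
    for (size_t k = 1; k < w.size(); ++k) {
      // nxt = (I + B/lam) cur
      nxt = cur;
      csc_axpy(n, Ap, Ai, Ax, cur.data(), nxt.data(), inv_lam);  // p block
      for (int l = 0; l < d; ++l) {
        const List dAl = dA[l];
        const IntegerVector dp = dAl["p"], di = dAl["i"];
        const NumericVector dx = dAl["x"];
        csc_axpy(n, Ap, Ai, Ax, cur.data() + n * (l + 1),
                 nxt.data() + n * (l + 1), inv_lam);
        csc_axpy(n, dp, di, dx, cur.data(), nxt.data() + n * (l + 1), inv_lam);
      }
      const double wk = w[k];
      if (wk > 0.0)
        for (int i = 0; i < nb; ++i) acc[i] += wk * nxt[i];
      cur.swap(nxt);
    }
    v = acc;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_cme_propagate(const int n, const IntegerVector Ap,
                                const IntegerVector Ai, const NumericVector Ax,
                                const List dA, const NumericVector v0,
                                const NumericVector rel_times,
                                const double q_max) {
  const int d = dA.size();
  const int nb = n * (d + 1);
  if (v0.size() != nb) stop("state vector length mismatch");
  // lam >= max_j |A_jj|
  double lam = 0.0;
  for (int j = 0; j < n; ++j)
    for (int ptr = Ap[j]; ptr < Ap[j + 1]; ++ptr)
      if (Ai[ptr] == j && -Ax[ptr] > lam) lam = -Ax[ptr];
  lam *= 1.0 + 1e-12;
  std::vector<double> v(v0.begin(), v0.end());
  NumericMatrix out(nb, rel_times.size());
  double t_prev = 0.0;
  for (int m = 0; m < rel_times.size(); ++m) {
    propagate_interval(n, d, Ap, Ai, Ax, dA, v, rel_times[m] - t_prev, lam,
                       q_max);
    t_prev = rel_times[m];
    for (int i = 0; i < nb; ++i) out(i, m) = v[i];
  }
  return out;
}
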