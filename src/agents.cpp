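// Sequential replay of the MPL / PVL / WSLS choice models.
//
// All functions walk a binary outcome sequence x (and, for likelihoods, a
// choice sequence y) trial by trial, maintaining the agent's learned state.
// The MPL expected-utility table E_j^eta has one row per option j in {0,1}
// and one column per history eta of the last k outcomes (2^k columns,
// encoded as bits: eta = sum_i x(t-k+i) * 2^i, oldest outcome in the lowest
// bit). theta = R_PosInf encodes the greedy (argmax) limit; ties give 0.5.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log1pexp_stable(double z) {
  if (z > 35.0) return z;
  if (z < -35.0) return std::exp(z);
  return std::log1p(std::exp(z));
}

// p1 and log choice probabilities from the softmax argument a = theta * (E1 - E0)
static inline double softmax_p1(double diff, double theta, bool greedy) {
  if (greedy) {
    if (diff > 0) return 1.0;
    if (diff < 0) return 0.0;
    return 0.5;
  }
  double a = theta * diff;
  return 1.0 / (1.0 + std::exp(-a));
}

struct MplReplay {
  int k, nh, T;
  double A, rho, theta;
  bool greedy;
  std::vector<double> E0, E1;
  const IntegerVector& x;

  MplReplay(const IntegerVector& x_, int k_, double A_, double rho_, double theta_)
    : k(k_), nh(1 << k_), T(x_.size()), A(A_), rho(rho_),
      theta(theta_), greedy(!R_finite(theta_)),
      E0(nh, 0.0), E1(nh, 0.0), x(x_) {}

  // history index before trial t (0-based t); valid only when t >= k
  inline int hist(int t) const {
    int idx = 0;
    for (int i = 0; i < k; ++i) idx |= (x[t - k + i] << i);
    return idx;
  }

  inline double prob1(int t) const {
    if (t < k) return 0.5;  // no full history yet: all-zero utilities
    int idx = hist(t);
    return softmax_p1(E1[idx] - E0[idx], theta, greedy);
  }

  // two-rate decay update after observing x[t]
  inline void update(int t) {
    double u1 = (double)x[t], u0 = 1.0 - u1;
    if (t < k) {
      // no realized history: global forgetting only (a no-op on a zero table)
      for (int h = 0; h < nh; ++h) { E0[h] *= A; E1[h] *= A; }
      return;
    }
    int idx = hist(t);
    for (int h = 0; h < nh; ++h) {
      if (h == idx) {
        E0[h] = A * rho * E0[h] + u0;
        E1[h] = A * rho * E1[h] + u1;
      } else {
        E0[h] *= A;
        E1[h] *= A;
      }
    }
  }
};

// [[Rcpp::export]]
List cpp_mpl_trace(IntegerVector x, int k, double A, double rho, double theta) {
  MplReplay rep(x, k, A, rho, theta);
  NumericVector p1(rep.T);
  for (int t = 0; t < rep.T; ++t) {
    p1[t] = rep.prob1(t);
    rep.update(t);
  }
  NumericMatrix E(2, rep.nh);
  for (int h = 0; h < rep.nh; ++h) { E(0, h) = rep.E0[h]; E(1, h) = rep.E1[h]; }
  return List::create(_["p1"] = p1, _["E"] = E);
}

// [[Rcpp::export]]
List cpp_mpl_simulate(IntegerVector x, int k, double A, double rho, double theta,
                      NumericVector u) {
  MplReplay rep(x, k, A, rho, theta);
  NumericVector p1(rep.T);
  IntegerVector y(rep.T);
  for (int t = 0; t < rep.T; ++t) {
    p1[t] = rep.prob1(t);
    y[t] = (u[t] < p1[t]) ? 1 : 0;
    rep.update(t);
  }
  return List::create(_["choices"] = y, _["probs"] = p1);
}

// [[Rcpp::export]]
double cpp_mpl_loglik(IntegerVector x, IntegerVector y, int k, double A,
                      double rho, double theta) {
  MplReplay rep(x, k, A, rho, theta);
  double ll = 0.0;
  for (int t = 0; t < rep.T; ++t) {
    if (rep.greedy || t < k) {
      double p1 = rep.prob1(t);
      double p = (y[t] == 1) ? p1 : 1.0 - p1;
      if (p <= 0.0) { ll = R_NegInf; break; }
      ll += std::log(p);
    } else {
      int idx = rep.hist(t);
      double a = theta * (rep.E1[idx] - rep.E0[idx]);
      ll += (y[t] == 1) ? -log1pexp_stable(-a) : -log1pexp_stable(a);
    }
    rep.update(t);
  }
  if (ll == R_NegInf) return R_NegInf;
  return ll;
}

// Log-likelihood under every memory length k = 0..kmax at once (one replay each).
// [[Rcpp::export]]
NumericVector cpp_mpl_loglik_allk(IntegerVector x, IntegerVector y, double A,
                                  double rho, double theta, int kmax) {
  NumericVector out(kmax + 1);
  for (int k = 0; k <= kmax; ++k)
    out[k] = cpp_mpl_loglik(x, y, k, A, rho, theta);
  return out;
}

struct WslsReplay {
  double pw, pl, tw, tl;
  WslsReplay(double pw1, double pl1, double tw_, double tl_)
    : pw(pw1), pl(pl1), tw(tw_), tl(tl_) {}

  // choice probability at trial t given previous choice/outcome (t > 0)
  inline double prob1(int yprev, int xprev) const {
    if (yprev == xprev)  // previous win: stay with probability pw
      return (yprev == 1) ? pw : 1.0 - pw;
    else                 // previous loss: shift with probability pl
      return (yprev == 1) ? 1.0 - pl : pl;
  }

  inline void update(int yt, int xt) {
    if (yt == xt) {
      pw += tw * (1.0 - pw);
      pl  = (1.0 - tl) * pl;
    } else {
      pw  = (1.0 - tw) * pw;
      pl += tl * (1.0 - pl);
    }
  }
};

// [[Rcpp::export]]
List cpp_wsls_simulate(IntegerVector x, double pw1, double pl1, double tw,
                       double tl, NumericVector u) {
  int T = x.size();
  WslsReplay rep(pw1, pl1, tw, tl);
  NumericVector p1(T);
  IntegerVector y(T);
  for (int t = 0; t < T; ++t) {
    p1[t] = (t == 0) ? 0.5 : rep.prob1(y[t - 1], x[t - 1]);
    y[t] = (u[t] < p1[t]) ? 1 : 0;
    rep.update(y[t], x[t]);
  }
  return List::create(_["choices"] = y, _["probs"] = p1);
}

// [[Rcpp::export]]
double cpp_wsls_loglik(IntegerVector x, IntegerVector y, double pw1, double pl1,
                       double tw, double tl) {
  int T = x.size();
  WslsReplay rep(pw1, pl1, tw, tl);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double p1 = (t == 0) ? 0.5 : rep.prob1(y[t - 1], x[t - 1]);
    double p = (y[t] == 1) ? p1 : 1.0 - p1;
    if (p <= 0.0) return R_NegInf;
    ll += std::log(p);
    rep.update(y[t], x[t]);
  }
  return ll;
}
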