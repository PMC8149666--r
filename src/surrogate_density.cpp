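// Mixture-of-experts surrogate: tempered log posterior over the unconstrained
// parameterization (component labels marginalized analytically), per-row
// log-likelihood, and posterior-predictive state densities averaged over
// MCMC draws. Hot path for both the slice sampler and the grid planner.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

namespace {

struct Layout {
  int K, dc, J, D, P;
  std::vector<int> Cj;   // categories per discrete variable
  std::vector<int> coff; // one-hot offset of each discrete variable
  int o_upi, o_m, o_ls, o_phi, o_b1, o_e2, o_e3;
};

Layout make_layout(int K, const IntegerVector& Cj, int dc) {
  Layout L;
  L.K = K; L.dc = dc; L.J = Cj.size(); L.D = 0;
  for (int j = 0; j < L.J; ++j) {
    L.coff.push_back(L.D);
    L.Cj.push_back(Cj[j]);
    L.D += Cj[j];
  }
  int p = 0;
  L.o_upi = p; p += K - 1;
  L.o_m   = p; p += K * dc;
  L.o_ls  = p; p += K * dc;
  L.o_phi = p; for (int j = 0; j < L.J; ++j) p += K * (L.Cj[j] - 1);
  L.o_b1  = p; p += K;
  L.o_e2  = p; p += K * dc;
  L.o_e3  = p; p += K * L.D;
  L.P = p;
  return L;
}

// Stan-style stick-breaking: u (len K-1) -> simplex p (len K); accumulates
// the log-Jacobian of the transform into lj.
void stick_break(const double* u, int K, double* p, double& lj) {
  double rest = 1.0;
  for (int k = 0; k < K - 1; ++k) {
    double adj = u[k] - std::log(static_cast<double>(K - 1 - k));
    double z = 1.0 / (1.0 + std::exp(-adj));
    p[k] = rest * z;
    lj += std::log(rest) + std::log(z) + std::log1p(-z);
    rest -= p[k];
  }
  p[K - 1] = rest;
}

struct Params {
  std::vector<double> logpi;          // K
  std::vector<double> m, s;           // K*dc (s = per-coordinate sd)
  std::vector<double> logphi;         // K*D (log category probabilities)
  std::vector<double> b1, e2, e3;     // K, K*dc, K*D
  double logjac;
  bool ok;
};

Params unpack(const double* th, const Layout& L) {
  Params P;
  P.ok = true;
  P.logjac = 0.0;
  std::vector<double> pi(L.K);
  if (L.K > 1) stick_break(th + L.o_upi, L.K, pi.data(), P.logjac);
  else pi[0] = 1.0;
  P.logpi.resize(L.K);
  for (int k = 0; k < L.K; ++k) {
    if (!(pi[k] > 0.0)) { P.ok = false; return P; }
    P.logpi[k] = std::log(pi[k]);
  }
  P.m.assign(th + L.o_m, th + L.o_m + L.K * L.dc);
  P.s.resize(L.K * L.dc);
  for (int i = 0; i < L.K * L.dc; ++i) {
    double ls = th[L.o_ls + i];
    P.s[i] = std::exp(ls);
    P.logjac += ls;
    if (!std::isfinite(P.s[i]) || P.s[i] <= 0.0) { P.ok = false; return P; }
  }
  P.logphi.assign(L.K * L.D, 0.0);
  {
    int pos = L.o_phi;
    for (int j = 0; j < L.J; ++j) {
      int C = L.Cj[j];
      for (int k = 0; k < L.K; ++k) {
        std::vector<double> pr(C);
        if (C > 1) stick_break(th + pos, C, pr.data(), P.logjac);
        else pr[0] = 1.0;
        pos += C - 1;
        for (int c = 0; c < C; ++c) {
          if (!(pr[c] > 0.0)) { P.ok = false; return P; }
          P.logphi[k * L.D + L.coff[j] + c] = std::log(pr[c]);
        }
      }
    }
  }
  P.b1.assign(th + L.o_b1, th + L.o_b1 + L.K);
  P.e2.assign(th + L.o_e2, th + L.o_e2 + L.K * L.dc);
  P.e3.assign(th + L.o_e3, th + L.o_e3 + L.K * L.D);
  return P;
}

double log_prior(const Params& P, const Layout& L, double m_sd,
                 double cauchy_scale, double b1_mean, double b1_sd) {
  // Dirichlet(1) terms on pi and phi are constant on the simplex and omitted.
  double lp = P.logjac;
  for (int i = 0; i < L.K * L.dc; ++i) {
    lp += R::dnorm(P.m[i], 0.0, m_sd, 1);
    double r = P.s[i] / cauchy_scale;
    lp += std::log(2.0 / M_PI) - std::log(cauchy_scale) - std::log1p(r * r);
  }
  for (int k = 0; k < L.K; ++k) lp += R::dnorm(P.b1[k], b1_mean, b1_sd, 1);
  for (int i = 0; i < L.K * L.dc; ++i) lp += -std::fabs(P.e2[i]) - M_LN2;
  for (int i = 0; i < L.K * L.D; ++i) lp += -std::fabs(P.e3[i]) - M_LN2;
  return lp;
}

// log p(x_cont, x_disc[, y] | theta) for one observation, labels marginalized.
double obs_loglik(const Params& P, const Layout& L, const double* xc,
                  const int* xd, double y, int task, double sigma,
                  bool include_y) {
  double best = -INFINITY;
  std::vector<double> lk(L.K);
  for (int k = 0; k < L.K; ++k) {
    double v = P.logpi[k];
    for (int d = 0; d < L.dc; ++d) {
      double s = P.s[k * L.dc + d];
      double z = (xc[d] - P.m[k * L.dc + d]) / s;
      v += -0.5 * z * z - std::log(s) - 0.5 * LOG2PI;
    }
    for (int j = 0; j < L.J; ++j)
      v += P.logphi[k * L.D + L.coff[j] + (xd[j] - 1)];
    if (include_y) {
      double mu = P.b1[k];
      for (int d = 0; d < L.dc; ++d) mu += P.e2[k * L.dc + d] * xc[d];
      for (int j = 0; j < L.J; ++j)
        mu += P.e3[k * L.D + L.coff[j] + (xd[j] - 1)];
      if (task == 0) {
        double z = (y - mu) / sigma;
        v += -0.5 * z * z - std::log(sigma) - 0.5 * LOG2PI;
      } else {
        double logth, log1mth;
        if (mu >= 0.0) {
          double e = std::exp(-mu);
          logth = -std::log1p(e);
          log1mth = -mu - std::log1p(e);
        } else {
          double e = std::exp(mu);
          logth = mu - std::log1p(e);
          log1mth = -std::log1p(e);
        }
        v += y * logth + (1.0 - y) * log1mth;
      }
    }
    lk[k] = v;
    if (v > best) best = v;
  }
  if (!std::isfinite(best)) return -INFINITY;
  double acc = 0.0;
  for (int k = 0; k < L.K; ++k) acc += std::exp(lk[k] - best);
  return best + std::log(acc);
}

} // namespace

// [[Rcpp::export]]
int ap_n_params(int K, int dc, IntegerVector Cj) {
  return make_layout(K, Cj, dc).P;
}

// Tempered log posterior: log prior + Jacobians + temp * sum_i loglik_i.
// [[Rcpp::export]]
double ap_log_posterior(NumericVector theta, NumericMatrix Xc, IntegerMatrix Xd,
                        NumericVector y, int task, double sigma, double m_sd,
                        double cauchy_scale, double b1_mean, double b1_sd,
                        double temp, int K, IntegerVector Cj) {
  const int n = Xc.nrow(), dc = Xc.ncol();
  Layout L = make_layout(K, Cj, dc);
  if (theta.size() != L.P) stop("theta has wrong length");
  Params P = unpack(REAL(theta), L);
  if (!P.ok) return -INFINITY;
  double lp = log_prior(P, L, m_sd, cauchy_scale, b1_mean, b1_sd);
  if (!std::isfinite(lp)) return -INFINITY;
  std::vector<double> xc(dc);
  std::vector<int> xd(L.J);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < dc; ++d) xc[d] = Xc(i, d);
    for (int j = 0; j < L.J; ++j) xd[j] = Xd(i, j);
    double v = obs_loglik(P, L, xc.data(), xd.data(), y[i], task, sigma, true);
    if (!std::isfinite(v)) return -INFINITY;
    ll += v;
  }
  return lp + temp * ll;
}

// Untempered per-row log-likelihood at one parameter draw (used for WBIC).
// [[Rcpp::export]]
NumericVector ap_loglik_rows(NumericVector theta, NumericMatrix Xc,
                             IntegerMatrix Xd, NumericVector y, int task,
                             double sigma, int K, IntegerVector Cj) {
  const int n = Xc.nrow(), dc = Xc.ncol();
  Layout L = make_layout(K, Cj, dc);
  if (theta.size() != L.P) stop("theta has wrong length");
  Params P = unpack(REAL(theta), L);
  NumericVector out(n);
  std::vector<double> xc(dc);
  std::vector<int> xd(L.J);
  for (int i = 0; i < n; ++i) {
    if (!P.ok) { out[i] = R_NegInf; continue; }
    for (int d = 0; d < dc; ++d) xc[d] = Xc(i, d);
    for (int j = 0; j < L.J; ++j) xd[j] = Xd(i, j);
    out[i] = obs_loglik(P, L, xc.data(), xd.data(), y[i], task, sigma, true);
  }
  return out;
}

// Posterior-predictive log density of states: for each row, the log of the
// mean over draws (rows of thetas) of the mixture density, computed with an
// online log-sum-exp so memory stays O(rows).
// [[Rcpp::export]]
NumericVector ap_state_logdensity(NumericMatrix thetas, NumericMatrix Xc,
                                  IntegerMatrix Xd, NumericVector y,
                                  int include_response, int task, double sigma,
                                  int K, IntegerVector Cj) {
  const int S = thetas.nrow();
  const int n = Xc.nrow(), dc = Xc.ncol();
  Layout L = make_layout(K, Cj, dc);
  if (thetas.ncol() != L.P) stop("draw matrix has wrong number of columns");
  std::vector<double> mx(n, -INFINITY), acc(n, 0.0);
  std::vector<double> th(L.P), xc(dc);
  std::vector<int> xd(L.J);
  for (int s = 0; s < S; ++s) {
    for (int p = 0; p < L.P; ++p) th[p] = thetas(s, p);
    Params P = unpack(th.data(), L);
    for (int i = 0; i < n; ++i) {
      double ld;
      if (!P.ok) ld = -INFINITY;
      else {
        for (int d = 0; d < dc; ++d) xc[d] = Xc(i, d);
        for (int j = 0; j < L.J; ++j) xd[j] = Xd(i, j);
        ld = obs_loglik(P, L, xc.data(), xd.data(), y[i], task, sigma,
                        include_response != 0);
      }
      if (!std::isfinite(ld)) continue;  // zero density from this draw
      if (ld > mx[i]) {
        acc[i] = acc[i] * std::exp(mx[i] - ld) + 1.0;
        mx[i] = ld;
      } else {
        acc[i] += std::exp(ld - mx[i]);
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = std::isfinite(mx[i]) ? mx[i] + std::log(acc[i]) - std::log((double)S)
                                  : R_NegInf;
  return out;
}
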