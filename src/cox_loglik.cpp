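#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Influence covariate of one reference train at absolute time t:
// exp(-(t - s)/tau) for the latest reference spike s <= t, 0 before the
// first spike.
static inline double zcov(const std::vector<double>& ref, double t, double tau) {
  if (ref.empty() || t < ref.front()) return 0.0;
  // last element <= t
  std::vector<double>::const_iterator it =
      std::upper_bound(ref.begin(), ref.end(), t);
  double s = *(it - 1);
  return std::exp(-(t - s) / tau);
}

// Partial log-likelihood of the modulated renewal Cox model, with analytic
// gradient and Hessian.  Each observation k is one target inter-spike
// interval: survival time len[k] on the backward-recurrence axis, event
// indicator, and absolute start time start[k].  The risk set of an event at
// elapsed time u holds every observation with len >= u, and covariates of
// observation k are evaluated at absolute time start[k] + u.  Ties in the
// event times are handled by the Breslow approximation (all events at one u
// share the full risk-set sum).  Within each risk set the linear predictor
// is centred at its maximum before exponentiation to guard overflow.
// [[Rcpp::export]]
List cox_loglik_cpp(NumericVector start, NumericVector len, IntegerVector event,
                    List refs, double tau, NumericVector beta) {
  const int n = start.size();
  const int p = refs.size();
  std::vector< std::vector<double> > R(p);
  for (int j = 0; j < p; ++j) {
    NumericVector rj = refs[j];
    R[j].assign(rj.begin(), rj.end());
  }

  // observations sorted by survival time descending: the risk set at any u
  // is a prefix of this order
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return len[a] > len[b]; });

  // unique event elapsed times (descending, so risk-set prefixes grow)
  std::vector<double> utimes;
  std::vector< std::vector<int> > events_at; // event obs indices per unique u
  {
    std::vector<int> ev;
    for (int i = 0; i < n; ++i) if (event[i]) ev.push_back(i);
    std::sort(ev.begin(), ev.end(),
              [&](int a, int b) { return len[a] > len[b]; });
    for (size_t k = 0; k < ev.size(); ++k) {
      if (utimes.empty() || len[ev[k]] != utimes.back()) {
        utimes.push_back(len[ev[k]]);
        events_at.push_back(std::vector<int>());
      }
      events_at.back().push_back(ev[k]);
    }
  }

  double ll = 0.0;
  NumericVector grad(p);
  NumericMatrix hess(p, p);
  std::vector<double> z(p), s1(p), s2(p * p);
  std::vector<double> zbuf;   // covariates of the whole risk set, row-major
  std::vector<double> eta;

  int rs = 0; // current risk-set prefix length
  for (size_t uq = 0; uq < utimes.size(); ++uq) {
    double u = utimes[uq];
    while (rs < n && len[ord[rs]] >= u) ++rs;
    zbuf.assign((size_t)rs * p, 0.0);
    eta.assign(rs, 0.0);
    double m = R_NegInf;
    for (int r = 0; r < rs; ++r) {
      int k = ord[r];
      double t = start[k] + u;
      double e = 0.0;
      for (int j = 0; j < p; ++j) {
        double zz = zcov(R[j], t, tau);
        zbuf[(size_t)r * p + j] = zz;
        e += beta[j] * zz;
      }
      eta[r] = e;
      if (e > m) m = e;
    }
    double S0 = 0.0;
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (int r = 0; r < rs; ++r) {
      double wgt = std::exp(eta[r] - m);
      S0 += wgt;
      const double* zr = &zbuf[(size_t)r * p];
      for (int j = 0; j < p; ++j) {
        s1[j] += wgt * zr[j];
        for (int l = j; l < p; ++l) s2[(size_t)j * p + l] += wgt * zr[j] * zr[l];
      }
    }
    double logS0 = std::log(S0) + m;
    // per-event contributions (Breslow: shared risk-set sums)
    for (size_t e = 0; e < events_at[uq].size(); ++e) {
      int k = events_at[uq][e];
      double t = start[k] + u;
      double etak = 0.0;
      for (int j = 0; j < p; ++j) {
        double zz = zcov(R[j], t, tau);
        etak += beta[j] * zz;
        grad[j] += zz - s1[j] / S0;
      }
      ll += etak - logS0;
      for (int j = 0; j < p; ++j)
        for (int l = j; l < p; ++l) {
          double v = s2[(size_t)j * p + l] / S0 - (s1[j] / S0) * (s1[l] / S0);
          hess(j, l) -= v;
          if (l != j) hess(l, j) -= v;
        }
    }
  }
  return List::create(_["loglik"] = ll, _["gradient"] = grad,
                      _["hessian"] = hess);
}

// Covariate matrix of all references over the risk set of every event:
// exposed for diagnostics and tests (one row per (event, at-risk obs) is
// not materialized; this returns covariates at the event times only).
// [[Rcpp::export]]
NumericMatrix event_covariates_cpp(NumericVector times, List refs, double tau) {
  const int n = times.size(), p = refs.size();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    NumericVector rj = refs[j];
    std::vector<double> R(rj.begin(), rj.end());
    for (int i = 0; i < n; ++i) out(i, j) = zcov(R, times[i], tau);
  }
  return out;
}

// Full Newton-Raphson fit of the modulated renewal partial likelihood.
// Influence covariates are independent of beta, so they are computed once
// per fit (cached per (risk-set observation, event time) pair) unless the
// cache would exceed `cache_limit` doubles, in which case they are
// re-evaluated on the fly.  Line-search (step-halving) evaluations use the
// cached covariates and skip gradient/Hessian work.  Returns the estimate,
// observed information, log-likelihood and convergence flag; the caller
// inspects the information matrix for singularity.
// [[Rcpp::export]]
List cox_newton_cpp(NumericVector start, NumericVector len, IntegerVector event,
                    List refs, double tau, int max_iter, double tol,
                    double cache_limit = 4e8) {
  const int n = start.size();
  const int p = refs.size();
  std::vector< std::vector<double> > R(p);
  for (int j = 0; j < p; ++j) {
    NumericVector rj = refs[j];
    R[j].assign(rj.begin(), rj.end());
  }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return len[a] > len[b]; });
  std::vector<double> utimes;
  std::vector< std::vector<int> > events_at;
  {
    std::vector<int> ev;
    for (int i = 0; i < n; ++i) if (event[i]) ev.push_back(i);
    std::sort(ev.begin(), ev.end(),
              [&](int a, int b) { return len[a] > len[b]; });
    for (size_t k = 0; k < ev.size(); ++k) {
      if (utimes.empty() || len[ev[k]] != utimes.back()) {
        utimes.push_back(len[ev[k]]);
        events_at.push_back(std::vector<int>());
      }
      events_at.back().push_back(ev[k]);
    }
  }
  const int nu = utimes.size();
  // risk-set prefix length per unique u, and cache offsets
  std::vector<int> rs_len(nu);
  std::vector<size_t> off(nu + 1, 0);
  {
    int rs = 0;
    for (int uq = 0; uq < nu; ++uq) {
      while (rs < n && len[ord[rs]] >= utimes[uq]) ++rs;
      rs_len[uq] = rs;
      off[uq + 1] = off[uq] + (size_t)rs;
    }
  }
  const size_t total_pairs = off[nu];
  const bool cached = (double)total_pairs * p <= cache_limit;
  std::vector<double> zc;
  if (cached) {
    zc.resize(total_pairs * (size_t)p);
    for (int uq = 0; uq < nu; ++uq) {
      double u = utimes[uq];
      for (int r = 0; r < rs_len[uq]; ++r) {
        int k = ord[r];
        double t = start[k] + u;
        double* zr = &zc[(off[uq] + r) * p];
        for (int j = 0; j < p; ++j) zr[j] = zcov(R[j], t, tau);
      }
    }
  }
  std::vector<double> zrow(p);
  // evaluate loglik (always) and grad/hess (optional) at beta
  NumericVector grad(p);
  NumericMatrix hess(p, p);
  std::vector<double> s1(p), s2((size_t)p * p);
  std::vector<double> eta;
  auto eval = [&](const std::vector<double>& beta, bool full) -> double {
    double ll = 0.0;
    if (full) {
      std::fill(grad.begin(), grad.end(), 0.0);
      std::fill(hess.begin(), hess.end(), 0.0);
    }
    for (int uq = 0; uq < nu; ++uq) {
      double u = utimes[uq];
      int rs = rs_len[uq];
      eta.assign(rs, 0.0);
      double m = R_NegInf;
      for (int r = 0; r < rs; ++r) {
        const double* zr;
        if (cached) zr = &zc[(off[uq] + r) * p];
        else {
          int k = ord[r];
          double t = start[k] + u;
          for (int j = 0; j < p; ++j) zrow[j] = zcov(R[j], t, tau);
          zr = &zrow[0];
        }
        double e = 0.0;
        for (int j = 0; j < p; ++j) e += beta[j] * zr[j];
        eta[r] = e;
        if (e > m) m = e;
      }
      double S0 = 0.0;
      if (full) {
        std::fill(s1.begin(), s1.end(), 0.0);
        std::fill(s2.begin(), s2.end(), 0.0);
      }
      for (int r = 0; r < rs; ++r) {
        double wgt = std::exp(eta[r] - m);
        S0 += wgt;
        if (full) {
          const double* zr;
          if (cached) zr = &zc[(off[uq] + r) * p];
          else {
            int k = ord[r];
            double t = start[k] + u;
            for (int j = 0; j < p; ++j) zrow[j] = zcov(R[j], t, tau);
            zr = &zrow[0];
          }
          for (int j = 0; j < p; ++j) {
            s1[j] += wgt * zr[j];
            for (int l = j; l < p; ++l)
              s2[(size_t)j * p + l] += wgt * zr[j] * zr[l];
          }
        }
      }
      double logS0 = std::log(S0) + m;
      int d = events_at[uq].size();
      for (int e = 0; e < d; ++e) {
        int k = events_at[uq][e];
        double t = start[k] + u;
        double etak = 0.0;
        for (int j = 0; j < p; ++j) {
          double zz = zcov(R[j], t, tau);
          etak += beta[j] * zz;
          if (full) grad[j] += zz - s1[j] / S0;
        }
        ll += etak - logS0;
      }
      if (full && d > 0) {
        for (int j = 0; j < p; ++j)
          for (int l = j; l < p; ++l) {
            double v = d * (s2[(size_t)j * p + l] / S0 -
                            (s1[j] / S0) * (s1[l] / S0));
            hess(j, l) -= v;
            if (l != j) hess(l, j) -= v;
          }
      }
    }
    return ll;
  };

  std::vector<double> beta(p, 0.0), nbeta(p);
  double ll = eval(beta, true);
  bool converged = false, singular = false;
  for (int iter = 0; iter < max_iter && !converged; ++iter) {
    // solve (-H) step = grad by Cholesky
    NumericMatrix A(p, p);
    for (int j = 0; j < p; ++j)
      for (int l = 0; l < p; ++l) A(j, l) = -hess(j, l);
    std::vector<double> L((size_t)p * p, 0.0), stp(grad.begin(), grad.end());
    bool ok = true;
    for (int j = 0; j < p && ok; ++j) {
      double d = A(j, j);
      for (int k0 = 0; k0 < j; ++k0) d -= L[(size_t)j * p + k0] * L[(size_t)j * p + k0];
      if (d <= 1e-12) { ok = false; break; }
      L[(size_t)j * p + j] = std::sqrt(d);
      for (int i = j + 1; i < p; ++i) {
        double v = A(i, j);
        for (int k0 = 0; k0 < j; ++k0) v -= L[(size_t)i * p + k0] * L[(size_t)j * p + k0];
        L[(size_t)i * p + j] = v / L[(size_t)j * p + j];
      }
    }
    if (!ok) { singular = true; break; }
    for (int i = 0; i < p; ++i) {
      double v = stp[i];
      for (int k0 = 0; k0 < i; ++k0) v -= L[(size_t)i * p + k0] * stp[k0];
      stp[i] = v / L[(size_t)i * p + i];
    }
    for (int i = p - 1; i >= 0; --i) {
      double v = stp[i];
      for (int k0 = i + 1; k0 < p; ++k0) v -= L[(size_t)k0 * p + i] * stp[k0];
      stp[i] = v / L[(size_t)i * p + i];
    }
    double maxstep = 0.0;
    double scale = 1.0;
    for (int h = 0; h < 30; ++h) {
      for (int j = 0; j < p; ++j) nbeta[j] = beta[j] + scale * stp[j];
      double nll = eval(nbeta, false);
      if (nll >= ll - 1e-12) break;
      scale *= 0.5;
    }
    for (int j = 0; j < p; ++j) {
      double d = std::fabs(scale * stp[j]);
      if (d > maxstep) maxstep = d;
      beta[j] += scale * stp[j];
    }
    ll = eval(beta, true);
    if (maxstep < tol) converged = true;
  }
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["loglik"] = ll, _["gradient"] = grad,
                      _["hessian"] = hess, _["converged"] = converged,
                      _["singular"] = singular);
}
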