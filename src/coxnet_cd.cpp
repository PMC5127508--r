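// Elastic-net Cox path solver: outer IRLS on the Breslow partial
// likelihood, inner cyclic coordinate descent with soft-thresholding,
// step halving to force monotone descent of the penalized objective.
// Inputs arrive pre-sorted by observed time (ascending); beta is
// order-free so no unsorting is needed.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct CoxData {
  const NumericMatrix& X;   // n x p, rows sorted by time
  const LogicalVector& ds;  // event flag, sorted
  const NumericVector& dk;  // events per distinct event time
  const IntegerVector& first; // 1-based index of first at-risk row per event time
  const IntegerVector& kof;   // # event times <= t_j, per row j
  int n, p, m;
};

// Breslow log partial likelihood with gradient/diagonal-Hessian in eta.
double cox_eval(const CoxData& d, const std::vector<double>& eta,
                std::vector<double>* g, std::vector<double>* w) {
  const int n = d.n, m = d.m;
  double c0 = eta[0];
  for (int i = 1; i < n; ++i) if (eta[i] > c0) c0 = eta[i];
  std::vector<double> theta(n), revcum(n + 1, 0.0);
  for (int i = 0; i < n; ++i) theta[i] = std::exp(eta[i] - c0);
  for (int i = n - 1; i >= 0; --i) revcum[i] = revcum[i + 1] + theta[i];
  std::vector<double> cum_dS(m + 1, 0.0), cum_dS2(m + 1, 0.0);
  double ll = 0.0;
  for (int k = 0; k < m; ++k) {
    double Sk = revcum[d.first[k] - 1];
    cum_dS[k + 1] = cum_dS[k] + d.dk[k] / Sk;
    cum_dS2[k + 1] = cum_dS2[k] + d.dk[k] / (Sk * Sk);
    ll -= d.dk[k] * (std::log(Sk) + c0);
  }
  for (int i = 0; i < n; ++i) {
    if (d.ds[i]) ll += eta[i];
    double A = cum_dS[d.kof[i]], B = cum_dS2[d.kof[i]];
    if (g) (*g)[i] = (d.ds[i] ? 1.0 : 0.0) - theta[i] * A;
    if (w) (*w)[i] = theta[i] * A - theta[i] * theta[i] * B;
  }
  return ll;
}

inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

double penalty(const std::vector<double>& b, double alpha) {
  double l1 = 0.0, l2 = 0.0;
  for (double v : b) { l1 += std::fabs(v); l2 += v * v; }
  return alpha * l1 + 0.5 * (1.0 - alpha) * l2;
}

} // namespace

// [[Rcpp::export(name = ".coxnet_path_cpp")]]
List coxnet_path_cpp(NumericMatrix Xs, LogicalVector ds, NumericVector dk,
                     IntegerVector first_at_risk, IntegerVector k_of_sample,
                     NumericVector lambda, double alpha, double tol,
                     int max_sweeps, int dfmax, bool error_on_nonconverge) {
  CoxData d{Xs, ds, dk, first_at_risk, k_of_sample,
            Xs.nrow(), Xs.ncol(), (int)dk.size()};
  const int n = d.n, p = d.p, L = lambda.size();
  NumericMatrix beta_mat(p, L);
  NumericVector objective(L);
  IntegerVector sweeps_out(L);
  List traces(L);
  int n_used = L;

  std::vector<double> beta(p, 0.0), eta(n, 0.0), g(n), w(n), r(n), xwx(p);
  double ll = cox_eval(d, eta, &g, &w);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l], lam1 = lam * alpha;
    double obj = -ll / n + lam * penalty(beta, alpha);
    std::vector<double> trace;
    trace.push_back(obj);
    int sweeps = 0;
    bool converged = false;
    while (!converged) {
      // quadratic approximation at the current eta
      for (int i = 0; i < n; ++i) {
        double wi = w[i] < 1e-9 ? 1e-9 : w[i];
        w[i] = wi;
        r[i] = g[i] / wi;           // working residual z - X beta
      }
      for (int j = 0; j < p; ++j) {
        const double* xj = &Xs(0, j);
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
        xwx[j] = s / n;
      }
      std::vector<double> b_new = beta;
      // cyclic CD with an active-set strategy: full sweeps locate the
      // working set, then sweeps cycle over nonzero coordinates until
      // stable, and a final full sweep checks for KKT violations
      const double thr = 1e-8;
      bool full_pass = true;
      for (;;) {
        double delta = 0.0;
        for (int j = 0; j < p; ++j) {
          if (!full_pass && b_new[j] == 0.0) continue;
          const double* xj = &Xs(0, j);
          double bj = b_new[j], u = 0.0;
          for (int i = 0; i < n; ++i) u += w[i] * xj[i] * r[i];
          u = u / n + xwx[j] * bj;
          double bn = soft(u, lam1) / (xwx[j] + lam * (1.0 - alpha));
          if (bn != bj) {
            double diff = bn - bj;
            for (int i = 0; i < n; ++i) r[i] -= xj[i] * diff;
            double ch = std::fabs(diff);
            if (ch > delta) delta = ch;
            b_new[j] = bn;
          }
        }
        ++sweeps;
        if (sweeps >= max_sweeps) break;
        if (full_pass) {
          if (delta < thr) break;      // converged, full sweep clean
          full_pass = false;
        } else if (delta < thr) {
          full_pass = true;            // active set stable: verify fully
        }
      }
      // step-halve toward the previous iterate if the objective rose
      double step = 1.0, obj_try = obj, ll_try = ll;
      std::vector<double> b_try, eta_try(n), g_try(n), w_try(n);
      for (;;) {
        b_try = beta;
        for (int j = 0; j < p; ++j) b_try[j] += step * (b_new[j] - beta[j]);
        for (int i = 0; i < n; ++i) {
          double e = 0.0;
          for (int j = 0; j < p; ++j)
            if (b_try[j] != 0.0) e += Xs(i, j) * b_try[j];
          eta_try[i] = e;
        }
        ll_try = cox_eval(d, eta_try, &g_try, &w_try);
        obj_try = -ll_try / n + lam * penalty(b_try, alpha);
        if (obj_try <= obj + 1e-12 || step < 1e-4) break;
        step *= 0.5;
      }
      if (obj_try > obj + 1e-12) {
        // no improving step: accept the current point and stop
        converged = true;
      } else {
        converged = std::fabs(obj - obj_try) <= tol * std::max(std::fabs(obj), 1.0);
        beta = b_try; eta = eta_try; g = g_try; w = w_try;
        ll = ll_try;
        if (obj_try < obj) obj = obj_try;
        trace.push_back(obj);
      }
      if (!converged && sweeps >= max_sweeps) {
        if (error_on_nonconverge)
          stop("coordinate descent did not converge in %d sweeps (lambda = %g)",
               max_sweeps, lam);
        n_used = l;                 // drop this and later lambdas
        break;
      }
    }
    if (n_used <= l) break;
    for (int j = 0; j < p; ++j) beta_mat(j, l) = beta[j];
    objective[l] = obj;
    sweeps_out[l] = sweeps;
    traces[l] = NumericVector(trace.begin(), trace.end());
    // refresh derivatives for the next lambda's warm start
    ll = cox_eval(d, eta, &g, &w);
    if (dfmax > 0 && l + 1 < L) {
      int nz = 0;
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) ++nz;
      if (nz >= dfmax) { n_used = l + 1; break; }
    }
  }
  return List::create(_["beta"] = beta_mat, _["objective"] = objective,
                      _["obj_traces"] = traces, _["sweeps"] = sweeps_out,
                      _["n_used"] = n_used);
}

// [[Rcpp::export(name = ".cox_pll_cpp")]]
double cox_pll_cpp(NumericVector eta_sorted, LogicalVector ds,
                   NumericVector dk, IntegerVector first_at_risk,
                   IntegerVector k_of_sample) {
  NumericMatrix dummy(1, 1);
  CoxData d{dummy, ds, dk, first_at_risk, k_of_sample,
            (int)eta_sorted.size(), 0, (int)dk.size()};
  std::vector<double> eta(eta_sorted.begin(), eta_sorted.end());
  return cox_eval(d, eta, nullptr, nullptr);
}
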