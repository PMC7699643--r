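#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Newton-Raphson fit of the Cox partial likelihood with Efron ties on
// counting-process (start, stop] data.  Written for the permutation-null
// engine, which refits the same design tens of thousands of times with only
// the event vector changing: ord_stop / ord_start (ascending sort orders,
// 0-based) are computed once in R and reused across calls.
//
// Risk set at event time t is {i : start_i < t <= stop_i}.  The sweep
// processes distinct event times in decreasing order, adding rows by
// decreasing stop and removing rows by decreasing start, so each row is
// touched at most twice per Newton iteration.

namespace {

struct Sums {
  double s0;
  std::vector<double> s1;
  std::vector<double> s2; // p x p, symmetric, stored dense
  explicit Sums(int p) : s0(0.0), s1(p, 0.0), s2(p * p, 0.0) {}
  void zero() {
    s0 = 0.0;
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
  }
  void add(const double *x, double w, int p, double sign) {
    s0 += sign * w;
    for (int a = 0; a < p; ++a) {
      const double wxa = sign * w * x[a];
      s1[a] += wxa;
      for (int b = 0; b <= a; ++b) s2[a * p + b] += wxa * x[b];
    }
  }
};

// Solve H x = g for symmetric positive-definite H (Cholesky, in place copies).
bool chol_solve(std::vector<double> H, std::vector<double> &g, int p) {
  // lower Cholesky
  for (int j = 0; j < p; ++j) {
    double d = H[j * p + j];
    for (int k = 0; k < j; ++k) d -= H[j * p + k] * H[j * p + k];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    H[j * p + j] = d;
    for (int i = j + 1; i < p; ++i) {
      double v = H[i * p + j];
      for (int k = 0; k < j; ++k) v -= H[i * p + k] * H[j * p + k];
      H[i * p + j] = v / d;
    }
  }
  // forward then back substitution
  for (int i = 0; i < p; ++i) {
    double v = g[i];
    for (int k = 0; k < i; ++k) v -= H[i * p + k] * g[k];
    g[i] = v / H[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double v = g[i];
    for (int k = i + 1; k < p; ++k) v -= H[k * p + i] * g[k];
    g[i] = v / H[i * p + i];
  }
  return true;
}

// Invert symmetric positive-definite matrix via Cholesky.
bool chol_inverse(std::vector<double> &H, int p) {
  std::vector<double> inv(p * p, 0.0);
  for (int j = 0; j < p; ++j) {
    std::vector<double> e(p, 0.0);
    e[j] = 1.0;
    std::vector<double> Hc(H);
    if (!chol_solve(Hc, e, p)) return false;
    for (int i = 0; i < p; ++i) inv[i * p + j] = e[i];
  }
  H = inv;
  return true;
}

} // namespace

class CoxSweep {
public:
  CoxSweep(const NumericMatrix &X, const NumericVector &start,
           const NumericVector &stop, const IntegerVector &event,
           const IntegerVector &ord_stop, const IntegerVector &ord_start)
      : X_(X), start_(start), stop_(stop), event_(event), ord_stop_(ord_stop),
        ord_start_(ord_start), n_(X.nrow()), p_(X.ncol()), risk(X.ncol()),
        death(X.ncol()) {
    // distinct event times, decreasing, with member rows grouped
    std::vector<int> ev;
    for (int i = 0; i < n_; ++i)
      if (event_[i] == 1) ev.push_back(i);
    std::sort(ev.begin(), ev.end(), [&](int a, int b) {
      return stop_[a] > stop_[b];
    });
    size_t i = 0;
    while (i < ev.size()) {
      size_t j = i;
      while (j < ev.size() && stop_[ev[j]] == stop_[ev[i]]) ++j;
      group_start.push_back(i);
      group_end.push_back(j);
      members.insert(members.end(), ev.begin() + i, ev.begin() + j);
      i = j;
    }
    xrow_.resize(p_);
  }

  int n_events() const { return static_cast<int>(members.size()); }

  // One pass over the data: accumulates loglik, and (if want_deriv) the
  // score vector and negative Hessian (observed information).
  double pass(const std::vector<double> &eta, bool want_deriv,
              std::vector<double> *grad, std::vector<double> *info) {
    const int p = p_;
    std::vector<double> w(n_);
    for (int i = 0; i < n_; ++i) w[i] = std::exp(eta[i]);

    risk.zero();
    double loglik = 0.0;
    if (want_deriv) {
      std::fill(grad->begin(), grad->end(), 0.0);
      std::fill(info->begin(), info->end(), 0.0);
    }

    int ia = n_ - 1; // pointer into ord_stop_ (descending stop)
    int ir = n_ - 1; // pointer into ord_start_ (descending start)
    for (size_t g = 0; g < group_start.size(); ++g) {
      const int first = members[group_start[g]];
      const double t = stop_[first];
      // add rows with stop >= t
      while (ia >= 0 && stop_[ord_stop_[ia]] >= t) {
        const int i = ord_stop_[ia];
        getrow(i);
        risk.add(xrow_.data(), w[i], p, +1.0);
        --ia;
      }
      // remove rows with start >= t
      while (ir >= 0 && start_[ord_start_[ir]] >= t) {
        const int i = ord_start_[ir];
        getrow(i);
        risk.add(xrow_.data(), w[i], p, -1.0);
        --ir;
      }
      // death-set sums
      death.zero();
      const int d = static_cast<int>(group_end[g] - group_start[g]);
      for (size_t m = group_start[g]; m < group_end[g]; ++m) {
        const int i = members[m];
        getrow(i);
        death.add(xrow_.data(), w[i], p, +1.0);
        loglik += eta[i];
        if (want_deriv)
          for (int a = 0; a < p; ++a) (*grad)[a] += xrow_[a];
      }
      for (int l = 0; l < d; ++l) {
        const double f = static_cast<double>(l) / d;
        const double d0 = risk.s0 - f * death.s0;
        loglik -= std::log(d0);
        if (want_deriv) {
          for (int a = 0; a < p; ++a) {
            const double m1a = (risk.s1[a] - f * death.s1[a]) / d0;
            (*grad)[a] -= m1a;
            for (int b = 0; b <= a; ++b) {
              const double m1b = (risk.s1[b] - f * death.s1[b]) / d0;
              const double v =
                  (risk.s2[a * p + b] - f * death.s2[a * p + b]) / d0 -
                  m1a * m1b;
              (*info)[a * p + b] += v;
              if (a != b) (*info)[b * p + a] += v;
            }
          }
        }
      }
    }
    return loglik;
  }

private:
  void getrow(int i) {
    for (int a = 0; a < p_; ++a) xrow_[a] = X_(i, a);
  }
  const NumericMatrix &X_;
  const NumericVector &start_, &stop_;
  const IntegerVector &event_;
  const IntegerVector &ord_stop_, &ord_start_;
  int n_, p_;
  Sums risk, death;
  std::vector<int> members;
  std::vector<size_t> group_start, group_end;
  std::vector<double> xrow_;
};

// [[Rcpp::export(name = ".cox_fit_cpp")]]
List cox_fit_cpp(NumericMatrix X, NumericVector start, NumericVector stop,
                 IntegerVector event, IntegerVector ord_stop,
                 IntegerVector ord_start, NumericVector init,
                 int iter_max = 25, double eps = 1e-9) {
  const int n = X.nrow(), p = X.ncol();
  if (start.size() != n || stop.size() != n || event.size() != n)
    Rcpp::stop("row length mismatch");
  CoxSweep sweep(X, start, stop, event, ord_stop, ord_start);
  if (sweep.n_events() == 0)
    Rcpp::stop("no events in data");

  std::vector<double> beta(p, 0.0);
  if (init.size() == p)
    for (int a = 0; a < p; ++a) beta[a] = init[a];

  std::vector<double> eta(n), grad(p), info(p * p);
  auto update_eta = [&](const std::vector<double> &b) {
    for (int i = 0; i < n; ++i) {
      double v = 0.0;
      for (int a = 0; a < p; ++a) v += X(i, a) * b[a];
      eta[i] = v;
    }
  };

  update_eta(beta);
  double loglik = sweep.pass(eta, true, &grad, &info);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= iter_max; ++iter) {
    std::vector<double> step(grad);
    std::vector<double> H(info);
    if (!chol_solve(H, step, p))
      Rcpp::stop("information matrix is singular (rank-deficient design)");
    std::vector<double> beta_new(p);
    double ll_new = 0.0;
    double halving = 1.0;
    bool ok = false, have_deriv = false;
    for (int h = 0; h < 6; ++h) {
      for (int a = 0; a < p; ++a) beta_new[a] = beta[a] + halving * step[a];
      update_eta(beta_new);
      // full Newton steps are almost always accepted, so compute the
      // derivatives in the same pass on the first attempt
      const bool deriv_now = (h == 0);
      ll_new = sweep.pass(eta, deriv_now, deriv_now ? &grad : nullptr,
                          deriv_now ? &info : nullptr);
      if (std::isfinite(ll_new) && ll_new >= loglik - 1e-12) {
        ok = true;
        have_deriv = deriv_now;
        break;
      }
      halving *= 0.5;
    }
    if (!ok) {
      // step rejected even after halving: restore derivatives at beta
      update_eta(beta);
      sweep.pass(eta, true, &grad, &info);
      break;
    }
    const double delta = ll_new - loglik;
    beta = beta_new;
    loglik = ll_new;
    if (!have_deriv) sweep.pass(eta, true, &grad, &info);
    if (std::fabs(delta) < eps * (std::fabs(loglik) + 1.0)) {
      converged = true;
      break;
    }
  }

  std::vector<double> var(info);
  if (!chol_inverse(var, p))
    Rcpp::stop("information matrix is singular at the optimum");

  NumericVector beta_out(p), se_out(p);
  NumericMatrix var_out(p, p);
  for (int a = 0; a < p; ++a) {
    beta_out[a] = beta[a];
    se_out[a] = std::sqrt(var[a * p + a]);
    for (int b = 0; b < p; ++b) var_out(a, b) = var[a * p + b];
  }
  return List::create(_["coef"] = beta_out, _["se"] = se_out,
                      _["var"] = var_out, _["loglik"] = loglik,
                      _["iter"] = iter, _["converged"] = converged,
                      _["n_events"] = sweep.n_events());
}
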