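#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Partial log-likelihood, score u and observed information imat for a Cox
// model at coefficient vector beta.  Data must be sorted by increasing time;
// risk sums are accumulated from the largest time downwards so each tie
// group is handled once.  efron = 1 applies the Efron correction inside tie
// groups, otherwise Breslow.
static double cox_eval(const NumericVector &time, const IntegerVector &status,
                       const NumericMatrix &X, const std::vector<double> &beta,
                       int efron, std::vector<double> &u,
                       std::vector<double> &imat) {
  const int n = X.nrow(), k = X.ncol();
  std::fill(u.begin(), u.end(), 0.0);
  std::fill(imat.begin(), imat.end(), 0.0);
  double loglik = 0.0, denom = 0.0;
  std::vector<double> a(k, 0.0), c2((size_t)k * k, 0.0);
  int i = n - 1;
  while (i >= 0) {
    const double t = time[i];
    double denom_d = 0.0, etasum = 0.0;
    std::vector<double> ad(k, 0.0), cd((size_t)k * k, 0.0), xsum(k, 0.0);
    int ndead = 0;
    int j = i;
    while (j >= 0 && time[j] == t) {
      double eta = 0.0;
      for (int m = 0; m < k; m++) eta += X(j, m) * beta[m];
      const double r = std::exp(eta);
      denom += r;
      for (int m = 0; m < k; m++) {
        a[m] += r * X(j, m);
        for (int l = 0; l <= m; l++) c2[(size_t)m * k + l] += r * X(j, m) * X(j, l);
      }
      if (status[j] == 1) {
        ndead++;
        etasum += eta;
        denom_d += r;
        for (int m = 0; m < k; m++) {
          xsum[m] += X(j, m);
          ad[m] += r * X(j, m);
          for (int l = 0; l <= m; l++) cd[(size_t)m * k + l] += r * X(j, m) * X(j, l);
        }
      }
      j--;
    }
    if (ndead > 0) {
      loglik += etasum;
      for (int m = 0; m < k; m++) u[m] += xsum[m];
      for (int l0 = 0; l0 < ndead; l0++) {
        const double f = efron ? (double)l0 / ndead : 0.0;
        const double d = denom - f * denom_d;
        loglik -= std::log(d);
        for (int m = 0; m < k; m++) {
          const double am = (a[m] - f * ad[m]) / d;
          u[m] -= am;
          for (int l = 0; l <= m; l++) {
            const double cml = (c2[(size_t)m * k + l] - f * cd[(size_t)m * k + l]) / d;
            const double al = (a[l] - f * ad[l]) / d;
            imat[(size_t)m * k + l] += cml - am * al;
          }
        }
      }
    }
    i = j;
  }
  for (int m = 0; m < k; m++)
    for (int l = 0; l < m; l++) imat[(size_t)l * k + m] = imat[(size_t)m * k + l];
  return loglik;
}

// Solve A x = b for symmetric positive-definite A (Cholesky, no pivoting).
// Returns false when a pivot collapses (singular information).
static bool chol_solve(std::vector<double> A, std::vector<double> b, int k,
                       std::vector<double> &x) {
  // factor A = L L'
  for (int j = 0; j < k; j++) {
    double d = A[(size_t)j * k + j];
    for (int m = 0; m < j; m++) d -= A[(size_t)j * k + m] * A[(size_t)j * k + m];
    if (d <= 1e-300) return false;
    d = std::sqrt(d);
    A[(size_t)j * k + j] = d;
    for (int i = j + 1; i < k; i++) {
      double s = A[(size_t)i * k + j];
      for (int m = 0; m < j; m++) s -= A[(size_t)i * k + m] * A[(size_t)j * k + m];
      A[(size_t)i * k + j] = s / d;
    }
  }
  // forward then backward substitution
  for (int i = 0; i < k; i++) {
    double s = b[i];
    for (int m = 0; m < i; m++) s -= A[(size_t)i * k + m] * b[m];
    b[i] = s / A[(size_t)i * k + i];
  }
  for (int i = k - 1; i >= 0; i--) {
    double s = b[i];
    for (int m = i + 1; m < k; m++) s -= A[(size_t)m * k + i] * b[m];
    b[i] = s / A[(size_t)i * k + i];
  }
  x = b;
  return true;
}

// Newton-Raphson maximization of the Cox partial log-likelihood with
// step-halving.  Aborts with monotone = TRUE when any |beta| exceeds
// beta_max during iteration (monotone-likelihood / separation guard).
// [[Rcpp::export(name = ".cox_fit_cpp")]]
List cox_fit_cpp(NumericVector time, IntegerVector status, NumericMatrix X,
                 int efron, int max_iter, double tol, double beta_max) {
  const int k = X.ncol();
  std::vector<double> beta(k, 0.0), u(k), imat((size_t)k * k), step(k);
  double ll = cox_eval(time, status, X, beta, efron, u, imat);
  const double loglik0 = ll;
  bool conv = false, mono = false, singular = false;
  int iter = 0;
  std::vector<double> unew(k), imatnew((size_t)k * k), newbeta(k);
  for (iter = 1; iter <= max_iter; iter++) {
    if (!chol_solve(imat, u, k, step)) { singular = true; break; }
    int halves = 0;
    double llnew;
    while (true) {
      for (int m = 0; m < k; m++) newbeta[m] = beta[m] + step[m];
      llnew = cox_eval(time, status, X, newbeta, efron, unew, imatnew);
      if (std::isfinite(llnew) && (llnew >= ll || halves >= 25)) break;
      for (int m = 0; m < k; m++) step[m] *= 0.5;
      halves++;
    }
    beta = newbeta;
    u = unew;
    imat = imatnew;
    for (int m = 0; m < k; m++)
      if (std::fabs(beta[m]) > beta_max) mono = true;
    if (mono) { ll = llnew; break; }
    if (std::fabs(llnew - ll) < tol) { ll = llnew; conv = true; break; }
    ll = llnew;
  }
  NumericVector beta_out(k), u_out(k);
  NumericMatrix imat_out(k, k);
  for (int m = 0; m < k; m++) {
    beta_out[m] = beta[m];
    u_out[m] = u[m];
    for (int l = 0; l < k; l++) imat_out(m, l) = imat[(size_t)m * k + l];
  }
  return List::create(_["coef"] = beta_out, _["score"] = u_out,
                      _["imat"] = imat_out, _["loglik0"] = loglik0,
                      _["loglik"] = ll, _["iter"] = iter,
                      _["converged"] = conv, _["monotone"] = mono,
                      _["singular"] = singular);
}

// Schoenfeld residuals at beta: one row per death (time-ascending), each the
// covariate of the dying subject minus the risk-set weighted mean; within a
// tie group of d deaths the Efron-adjusted means are averaged over the d
// correction steps so residuals sum to the score vector.  Also returns the
// per-death risk-set covariance contribution (k x k x ndead array, same
// averaging convention) needed for the exact proportional-hazards score
// test variance.
// [[Rcpp::export(name = ".schoenfeld_cpp")]]
List schoenfeld_cpp(NumericVector time, IntegerVector status, NumericMatrix X,
                    NumericVector beta, int efron) {
  const int n = X.nrow(), k = X.ncol();
  int ndead = 0;
  for (int i = 0; i < n; i++) ndead += (status[i] == 1);
  NumericMatrix res(ndead, k);
  NumericVector dtimes(ndead);
  NumericVector vmat((R_xlen_t)k * k * ndead);
  vmat.attr("dim") = IntegerVector::create(k, k, ndead);
  double denom = 0.0;
  std::vector<double> a(k, 0.0), c2((size_t)k * k, 0.0);
  int row = ndead; // filled backwards so output ends up time-ascending
  int i = n - 1;
  while (i >= 0) {
    const double t = time[i];
    double denom_d = 0.0;
    std::vector<double> ad(k, 0.0), cd((size_t)k * k, 0.0);
    std::vector<int> dying;
    int j = i;
    while (j >= 0 && time[j] == t) {
      double eta = 0.0;
      for (int m = 0; m < k; m++) eta += X(j, m) * beta[m];
      const double r = std::exp(eta);
      denom += r;
      for (int m = 0; m < k; m++) {
        a[m] += r * X(j, m);
        for (int l = 0; l <= m; l++) c2[(size_t)m * k + l] += r * X(j, m) * X(j, l);
      }
      if (status[j] == 1) {
        dying.push_back(j);
        denom_d += r;
        for (int m = 0; m < k; m++) {
          ad[m] += r * X(j, m);
          for (int l = 0; l <= m; l++) cd[(size_t)m * k + l] += r * X(j, m) * X(j, l);
        }
      }
      j--;
    }
    const int d = (int)dying.size();
    if (d > 0) {
      std::vector<double> xbar(k, 0.0), vbar((size_t)k * k, 0.0);
      for (int l0 = 0; l0 < d; l0++) {
        const double f = efron ? (double)l0 / d : 0.0;
        const double dd = denom - f * denom_d;
        std::vector<double> mu(k);
        for (int m = 0; m < k; m++) {
          mu[m] = (a[m] - f * ad[m]) / dd;
          xbar[m] += mu[m] / d;
        }
        for (int m = 0; m < k; m++)
          for (int l = 0; l <= m; l++) {
            const double cml = (c2[(size_t)m * k + l] - f * cd[(size_t)m * k + l]) / dd;
            vbar[(size_t)m * k + l] += (cml - mu[m] * mu[l]) / d;
          }
      }
      for (int m = 0; m < k; m++)
        for (int l = 0; l < m; l++) vbar[(size_t)l * k + m] = vbar[(size_t)m * k + l];
      for (int q = 0; q < d; q++) {
        row--;
        dtimes[row] = t;
        for (int m = 0; m < k; m++) res(row, m) = X(dying[q], m) - xbar[m];
        for (int m = 0; m < k; m++)
          for (int l = 0; l < k; l++)
            vmat[(R_xlen_t)row * k * k + (R_xlen_t)l * k + m] = vbar[(size_t)l * k + m];
      }
    }
    i = j;
  }
  return List::create(_["residuals"] = res, _["time"] = dtimes,
                      _["vmat"] = vmat);
}
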