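#include <Rcpp.h>
using namespace Rcpp;

// Exact conditional logistic likelihood for matched strata.
//
// Per stratum with members x_1..x_n (m of them cases) the contribution is
//   sum_{cases} x_i'beta - log sum_{|S| = m} exp(sum_{i in S} x_i'beta).
// The denominator and its derivatives are computed by the standard recursion
// over elementary sums in the weights w_i = exp(x_i'beta): with
//   B_j(k)  = sum over size-k subsets of the first j members of prod w,
//   Bg_j(k) = same sum weighted by the subset's summed covariate vector,
//   Bh_j(k) = same weighted by the outer product of that vector,
// one has B_j(k) = B_{j-1}(k) + w_j B_{j-1}(k-1) and the matching updates for
// Bg and Bh. No subset is ever enumerated explicitly. The linear predictor is
// centered at its stratum maximum for overflow safety.
//
// strata: list of integer vectors of 0-based row indices into X / y.
// order: 0 = loglik only, 1 = + gradient, 2 = + gradient and Hessian.
// [[Rcpp::export(name = ".clogit_derivs_cpp")]]
List clogit_derivs_cpp(NumericVector beta, NumericMatrix X, IntegerVector y,
                       List strata, int order) {
  const int p = beta.size();
  double ll = 0.0;
  NumericVector grad(p);
  NumericMatrix info(p, p); // negative Hessian (observed information)

  std::vector<double> B, Bprev;
  std::vector<double> Bg, Bgprev;
  std::vector<double> Bh, Bhprev;

  for (int s = 0; s < strata.size(); ++s) {
    IntegerVector idx = strata[s];
    const int n = idx.size();
    int m = 0;
    for (int j = 0; j < n; ++j) m += y[idx[j]];
    if (m == 0 || m == n) continue; // uninformative

    // linear predictors, centered
    std::vector<double> eta(n);
    double cmax = R_NegInf;
    for (int j = 0; j < n; ++j) {
      double e = 0.0;
      const int r = idx[j];
      for (int k = 0; k < p; ++k) e += X(r, k) * beta[k];
      eta[j] = e;
      if (e > cmax) cmax = e;
    }

    const int K = m + 1;
    B.assign(K, 0.0); B[0] = 1.0;
    if (order >= 1) Bg.assign((size_t)K * p, 0.0);
    if (order >= 2) Bh.assign((size_t)K * p * p, 0.0);

    for (int j = 0; j < n; ++j) {
      const double w = std::exp(eta[j] - cmax);
      const int r = idx[j];
      const int kmax = std::min(j + 1, m);
      for (int k = kmax; k >= 1; --k) {
        const double bprev = B[k - 1];
        if (order >= 2) {
          double* h = &Bh[(size_t)k * p * p];
          const double* hprev = &Bh[(size_t)(k - 1) * p * p];
          const double* gprev = &Bg[(size_t)(k - 1) * p];
          for (int a = 0; a < p; ++a) {
            const double xa = X(r, a);
            for (int b = 0; b < p; ++b) {
              const double xb = X(r, b);
              h[a * p + b] += w * (hprev[a * p + b] + xa * gprev[b] +
                                   gprev[a] * xb + xa * xb * bprev);
            }
          }
        }
        if (order >= 1) {
          double* g = &Bg[(size_t)k * p];
          const double* gprev = &Bg[(size_t)(k - 1) * p];
          for (int a = 0; a < p; ++a) g[a] += w * (gprev[a] + X(r, a) * bprev);
        }
        B[k] += w * bprev;
      }
    }

    // numerator: sum over cases
    double num = 0.0;
    std::vector<double> sx(p, 0.0);
    for (int j = 0; j < n; ++j) {
      const int r = idx[j];
      if (y[r] == 1) {
        num += eta[j];
        if (order >= 1) for (int a = 0; a < p; ++a) sx[a] += X(r, a);
      }
    }
    const double Bm = B[m];
    ll += num - m * cmax - std::log(Bm);
    if (order >= 1) {
      const double* gm = order >= 1 ? &Bg[(size_t)m * p] : nullptr;
      for (int a = 0; a < p; ++a) grad[a] += sx[a] - gm[a] / Bm;
      if (order >= 2) {
        const double* hm = &Bh[(size_t)m * p * p];
        for (int a = 0; a < p; ++a)
          for (int b = 0; b < p; ++b)
            info(a, b) += hm[a * p + b] / Bm - (gm[a] / Bm) * (gm[b] / Bm);
      }
    }
  }

  List out = List::create(Named("loglik") = ll);
  if (order >= 1) out["gradient"] = grad;
  if (order >= 2) out["information"] = info;
  return out;
}
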