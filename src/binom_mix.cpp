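#include <Rcpp.h>
using namespace Rcpp;

static inline double clampq(double q) {
  if (q < 1e-6) return 1e-6;
  if (q > 1.0 - 1e-6) return 1.0 - 1e-6;
  return q;
}

// EM for a k-component binomial mixture over multi-sample CCF vectors.
// A, D: n x S alt/depth counts; C: n x S clonal allele fractions (the
// VAF a fully clonal mutation would show); phi0: k x S initial cluster
// CCFs. Log-likelihood omits the binomial coefficients (constant in
// the parameters); the caller adds them back. M-step: per-(cluster,
// sample) weighted binomial MLE of phi, moment start plus Newton
// refinement, clamped to [0, 1].
// [[Rcpp::export]]
List binom_mix_em_cpp(NumericMatrix A, NumericMatrix D,
                      NumericMatrix C, NumericMatrix phi0,
                      double tol, int maxit) {
  const int n = A.nrow(), S = A.ncol(), k = phi0.nrow();
  NumericMatrix phi = clone(phi0);
  std::vector<double> pi_k(k, 1.0 / k);
  NumericMatrix L(n, k), R(n, k);
  double ll = R_NegInf, ll_old = R_NegInf;
  int iter = 0;
  for (iter = 0; iter < maxit; ++iter) {
    // E-step
    for (int j = 0; j < k; ++j) {
      double lpj = std::log(pi_k[j]);
      for (int i = 0; i < n; ++i) {
        double s = lpj;
        for (int c = 0; c < S; ++c) {
          double q = clampq(phi(j, c) * C(i, c));
          s += A(i, c) * std::log(q) +
            (D(i, c) - A(i, c)) * std::log1p(-q);
        }
        L(i, j) = s;
      }
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = L(i, 0);
      for (int j = 1; j < k; ++j) if (L(i, j) > mx) mx = L(i, j);
      double rs = 0.0;
      for (int j = 0; j < k; ++j) { R(i, j) = std::exp(L(i, j) - mx);
        rs += R(i, j); }
      ll += mx + std::log(rs);
      for (int j = 0; j < k; ++j) R(i, j) /= rs;
    }
    if (R_finite(ll_old) && std::fabs(ll - ll_old) < tol) break;
    ll_old = ll;
    // M-step
    for (int j = 0; j < k; ++j) {
      double wsum = 0.0;
      for (int i = 0; i < n; ++i) wsum += R(i, j);
      pi_k[j] = std::max(wsum / n, 1e-12);
      if (wsum < 1e-8) continue;
      for (int c = 0; c < S; ++c) {
        double num = 0.0, den = 0.0;
        for (int i = 0; i < n; ++i) {
          num += R(i, j) * A(i, c);
          den += R(i, j) * D(i, c) * C(i, c);
        }
        double ph = num / std::max(den, 1e-12);
        if (ph < 1e-6) ph = 1e-6;
        if (ph > 1.0) ph = 1.0;
        for (int it2 = 0; it2 < 3; ++it2) {
          double g = 0.0, h = 0.0;
          for (int i = 0; i < n; ++i) {
            double w = R(i, j);
            if (w < 1e-12) continue;
            double cc = C(i, c);
            double q = clampq(ph * cc);
            double dm = D(i, c) - A(i, c);
            g += w * (A(i, c) / ph - dm * cc / (1.0 - q));
            h += w * (-A(i, c) / (ph * ph) -
                      dm * cc * cc / ((1.0 - q) * (1.0 - q)));
          }
          if (!R_finite(g) || !R_finite(h) || h >= 0) break;
          ph -= g / h;
          if (ph < 1e-6) ph = 1e-6;
          if (ph > 1.0) ph = 1.0;
        }
        phi(j, c) = ph;
      }
      double tot = 0.0;
      for (int jj = 0; jj < k; ++jj) tot += pi_k[jj];
      for (int jj = 0; jj < k; ++jj) pi_k[jj] /= tot;
    }
  }
  return List::create(_["phi"] = phi,
                      _["pi"] = NumericVector(pi_k.begin(), pi_k.end()),
                      _["loglik"] = ll, _["iterations"] = iter);
}
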