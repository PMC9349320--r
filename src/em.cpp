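#include <Rcpp.h>
using namespace Rcpp;

// multinomial mixture log-likelihood (up to the multinomial constant)
static double mix_ll(const std::vector<double>& e,
                     const NumericMatrix& P,
                     const NumericVector& counts) {
  const int J = P.nrow(), K = P.ncol();
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    if (counts[j] <= 0.0) continue;
    double pj = 0.0;
    for (int k = 0; k < K; ++k) pj += e[k] * P(j, k);
    ll += counts[j] * std::log(pj > 1e-300 ? pj : 1e-300);
  }
  return ll;
}

// one EM update of the exposure vector
static void em_map(const std::vector<double>& e,
                   std::vector<double>& out,
                   const NumericMatrix& P,
                   const NumericVector& counts, double n) {
  const int J = P.nrow(), K = P.ncol();
  std::fill(out.begin(), out.end(), 0.0);
  for (int j = 0; j < J; ++j) {
    if (counts[j] <= 0.0) continue;
    double pj = 0.0;
    for (int k = 0; k < K; ++k) pj += e[k] * P(j, k);
    if (pj <= 1e-300) continue;
    double w = counts[j] / pj;
    for (int k = 0; k < K; ++k) out[k] += e[k] * P(j, k) * w;
  }
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += out[k];
  if (tot > 0) for (int k = 0; k < K; ++k) out[k] /= tot;
  else for (int k = 0; k < K; ++k) out[k] = 1.0 / K;
  (void)n;
}

// project onto the simplex, flooring coordinates at a tiny positive
// value: an exact zero is a fixed point of the multiplicative EM map,
// so a zero introduced by extrapolation could never be revived and
// the iteration could stall at a non-optimal boundary
static void simplex_clamp(std::vector<double>& e) {
  double tot = 0.0;
  for (size_t k = 0; k < e.size(); ++k) {
    if (e[k] < 1e-10) e[k] = 1e-10;
    tot += e[k];
  }
  for (size_t k = 0; k < e.size(); ++k) e[k] /= tot;
}

// Maximum-likelihood multinomial-mixture exposures by SQUAREM-
// accelerated EM (squared extrapolation of the EM map with a monotone
// fallback to the plain double EM step). Converges when a full cycle
// improves the log-likelihood by less than tol.
// [[Rcpp::export]]
List em_exposures_cpp(NumericVector counts, NumericMatrix P,
                      NumericVector e0, double tol, int maxit) {
  const int K = P.ncol();
  double n = 0.0;
  for (int j = 0; j < counts.size(); ++j) n += counts[j];
  std::vector<double> e(e0.begin(), e0.end());
  simplex_clamp(e);
  // keep the start interior so EM can move any coordinate
  for (int k = 0; k < K; ++k) if (e[k] < 1e-8) e[k] = 1e-8;
  simplex_clamp(e);
  std::vector<double> e1(K), e2(K), eacc(K);
  double ll = mix_ll(e, P, counts);
  int evals = 0;
  for (int cyc = 0; cyc < maxit; ++cyc) {
    em_map(e, e1, P, counts, n);
    em_map(e1, e2, P, counts, n);
    evals += 2;
    double rr = 0.0, vv = 0.0;
    for (int k = 0; k < K; ++k) {
      double r = e1[k] - e[k];
      double v = e2[k] - e1[k] - r;
      rr += r * r; vv += v * v;
    }
    double ll_new;
    if (vv > 1e-30) {
      double alpha = -std::sqrt(rr / vv);
      if (alpha > -1.0) alpha = -1.0;
      for (int k = 0; k < K; ++k) {
        double r = e1[k] - e[k];
        double v = e2[k] - e1[k] - r;
        eacc[k] = e[k] - 2.0 * alpha * r + alpha * alpha * v;
      }
      simplex_clamp(eacc);
      double ll_acc = mix_ll(eacc, P, counts);
      double ll2 = mix_ll(e2, P, counts);
      if (ll_acc >= ll2) { e = eacc; ll_new = ll_acc; }
      else { e = e2; ll_new = ll2; }
    } else {
      e = e2;
      ll_new = mix_ll(e2, P, counts);
    }
    if (ll_new - ll < tol && cyc > 0) { ll = std::max(ll, ll_new);
      break; }
    ll = ll_new;
  }
  return List::create(_["exposures"] = NumericVector(e.begin(), e.end()),
                      _["loglik"] = ll, _["iterations"] = evals);
}
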