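#include <Rcpp.h>
using namespace Rcpp;

// Fused Adam update: one pass over the parameter block instead of a dozen
// vectorized R passes. Returns fresh vectors (functional semantics; nothing
// is modified in place).
// [[Rcpp::export]]
List adam_update_cpp(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double beta1, double beta2,
                     double eps, double t, double l2) {
  R_xlen_t n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  double bc1 = 1.0 - std::pow(beta1, t);
  double bc2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i] + l2 * p[i];
    double mi = beta1 * m[i] + (1.0 - beta1) * gi;
    double vi = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    m2[i] = mi;
    v2[i] = vi;
    p2[i] = p[i] - lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
  if (p.hasAttribute("dim")) p2.attr("dim") = p.attr("dim");
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}

// In-place variant used by the training loop: updates the parameter block and
// the moment buffers directly (they are owned exclusively by the network being
// fitted and its optimizer state; nothing else may alias them).
// [[Rcpp::export]]
void adam_update_inplace_cpp(NumericVector p, NumericVector g, NumericVector m,
                             NumericVector v, double lr, double beta1,
                             double beta2, double eps, double t, double l2) {
  R_xlen_t n = p.size();
  double bc1 = 1.0 - std::pow(beta1, t);
  double bc2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i] + l2 * p[i];
    double mi = beta1 * m[i] + (1.0 - beta1) * gi;
    double vi = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    m[i] = mi;
    v[i] = vi;
    p[i] -= lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
}
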