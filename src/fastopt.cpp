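#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Fused Adam update for one parameter block: reads x and g, updates the
// moment buffers m and v in place (they are owned exclusively by the
// optimizer environment), and returns the new parameter values in a single
// memory pass. Keeping this in C++ avoids eight full-vector temporaries per
// block per epoch, which dominates runtime for the first encoder layer.
// [[Rcpp::export]]
NumericVector adam_step_cpp(NumericVector x, NumericVector g,
                            NumericVector m, NumericVector v,
                            int t, double lr,
                            double beta1, double beta2, double eps) {
  R_xlen_t n = x.size();
  NumericVector out(no_init(n));
  double c1 = 1.0 - std::pow(beta1, (double)t);
  double c2 = 1.0 - std::pow(beta2, (double)t);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mi = beta1 * m[i] + (1.0 - beta1) * g[i];
    double vi = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    m[i] = mi;
    v[i] = vi;
    out[i] = x[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  return out;
}

// Fused SGD-with-momentum update; velocity buffer updated in place.
// [[Rcpp::export]]
NumericVector sgd_step_cpp(NumericVector x, NumericVector g,
                           NumericVector vel, double lr, double momentum) {
  R_xlen_t n = x.size();
  NumericVector out(no_init(n));
  for (R_xlen_t i = 0; i < n; ++i) {
    double vi = momentum * vel[i] + g[i];
    vel[i] = vi;
    out[i] = x[i] - lr * vi;
  }
  return out;
}

// One step of the learning-rate-free D-Adaptation SGD for one block:
// accumulates s += lambda * g in place and returns the updated parameters;
// the scalar bookkeeping (d, ||s||, sum lambda^2 ||g||^2) happens in R.
// [[Rcpp::export]]
List dadapt_block_cpp(NumericVector x, NumericVector g, NumericVector s,
                      double lambda) {
  R_xlen_t n = x.size();
  NumericVector out(no_init(n));
  double gsq = 0.0, ssq = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    gsq += gi * gi;
    double si = s[i] + lambda * gi;
    s[i] = si;
    ssq += si * si;
    out[i] = x[i] - lambda * gi;
  }
  return List::create(_["x"] = out, _["gsq"] = gsq, _["ssq"] = ssq);
}
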