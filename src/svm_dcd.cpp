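// Dual coordinate descent for the L1-loss linear SVM
//   min_w  0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w' x_i)
// solved in the dual with box constraints 0 <= alpha_i <= C.  A bias term is
// handled by augmenting every sample with a constant feature.  The update
// order is a seeded permutation per epoch so fits are deterministic.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Lcg {
  uint64_t s;
  explicit Lcg(uint64_t seed) : s(seed * 6364136223846793005ULL + 1442695040888963407ULL) {}
  uint64_t next() {
    s = s * 6364136223846793005ULL + 1442695040888963407ULL;
    return s >> 33;
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

} // namespace

// [[Rcpp::export(name = ".svm_dcd_fit")]]
List svm_dcd_fit(NumericMatrix X, NumericVector y, double cost,
                 double bias, int max_epochs, double tol, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (cost <= 0) stop("cost must be positive");

  std::vector<double> w(p, 0.0);
  double wb = 0.0; // weight of the constant bias feature
  std::vector<double> alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double q = bias * bias;
    for (int k = 0; k < p; ++k) q += X(i, k) * X(i, k);
    qii[i] = q;
  }

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Lcg rng(static_cast<uint64_t>(seed) + 0x9E3779B97F4A7C15ULL);

  int epoch = 0;
  bool converged = false;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(idx[i], idx[j]);
    }
    double pg_max = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      double wx = wb * bias;
      for (int k = 0; k < p; ++k) wx += w[k] * X(i, k);
      const double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= cost && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > pg_max) pg_max = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > cost) a_new = cost;
        const double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          for (int k = 0; k < p; ++k) w[k] += delta * X(i, k);
          wb += delta * bias;
          alpha[i] = a_new;
        }
      }
    }
    if (pg_max < tol) { converged = true; break; }
  }

  // objectives (duality-gap diagnostics)
  double wnorm2 = wb * wb;
  for (int k = 0; k < p; ++k) wnorm2 += w[k] * w[k];
  double hinge = 0.0, asum = 0.0;
  for (int i = 0; i < n; ++i) {
    double wx = wb * bias;
    for (int k = 0; k < p; ++k) wx += w[k] * X(i, k);
    const double m = 1.0 - y[i] * wx;
    if (m > 0) hinge += m;
    asum += alpha[i];
  }
  const double primal = 0.5 * wnorm2 + cost * hinge;
  const double dual = asum - 0.5 * wnorm2;

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = wb * bias,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch + 1,
                      _["converged"] = converged,
                      _["primal_objective"] = primal,
                      _["dual_objective"] = dual);
}
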