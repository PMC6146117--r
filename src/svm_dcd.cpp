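#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized hinge-loss linear SVM:
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w' x_i)
// solved in the dual with one alpha per sample, alpha_i in [0, C].
// Xt holds features x samples in compressed-sparse-column layout so each
// sample's nonzeros are contiguous. The coordinate order is reshuffled each
// epoch with a private PRNG seeded by `seed`, making the fit fully
// deterministic for fixed inputs. Convergence: largest projected gradient
// magnitude in an epoch below `tol`, or `max_epochs`.
// [[Rcpp::export]]
Rcpp::List svm_dcd(S4 Xt, NumericVector y, double C, double tol,
                   int max_epochs, int seed) {
  IntegerVector colptr = Xt.slot("p");
  IntegerVector rowind = Xt.slot("i");
  NumericVector xval = Xt.slot("x");
  IntegerVector dim = Xt.slot("Dim");
  const int nfeat = dim[0];
  const int n = dim[1];

  NumericVector w(nfeat);
  std::vector<double> alpha(n, 0.0), qdiag(n, 0.0);
  for (int s = 0; s < n; ++s) {
    double q = 0.0;
    for (int k = colptr[s]; k < colptr[s + 1]; ++k) q += xval[k] * xval[k];
    qdiag[s] = q;
  }

  std::vector<int> order(n);
  for (int s = 0; s < n; ++s) order[s] = s;
  uint64_t state = 0x9E3779B97F4A7C15ULL ^ (uint64_t)(uint32_t)seed;
  auto next32 = [&state]() -> uint32_t {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    return (uint32_t)(state >> 33);
  };

  int epochs_run = 0;
  double max_pg = 0.0;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (int s = n - 1; s > 0; --s) {
      int j = (int)(next32() % (uint32_t)(s + 1));
      std::swap(order[s], order[j]);
    }
    max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int s = order[t];
      if (qdiag[s] <= 0.0) continue;
      double g = 0.0;
      for (int k = colptr[s]; k < colptr[s + 1]; ++k)
        g += w[rowind[k]] * xval[k];
      g = g * y[s] - 1.0;
      double pg = g;
      if (alpha[s] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[s] >= C && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (pg != 0.0) {
        const double a_old = alpha[s];
        const double a_new = std::min(std::max(a_old - g / qdiag[s], 0.0), C);
        alpha[s] = a_new;
        const double d = (a_new - a_old) * y[s];
        if (d != 0.0)
          for (int k = colptr[s]; k < colptr[s + 1]; ++k)
            w[rowind[k]] += d * xval[k];
      }
    }
    epochs_run = epoch + 1;
    if (max_pg < tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("epochs") = epochs_run,
                            Rcpp::Named("max_pg") = max_pg);
}
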