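#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Gaussian kernel matrix K[i, j] = exp(-sigma * ||x1_i - x2_j||^2).
// sigma multiplies the squared distance (kernlab rbfdot convention).
// [[Rcpp::export(name = ".rbfKernelCpp")]]
NumericMatrix rbfKernelCpp(NumericMatrix x1, NumericMatrix x2, double sigma) {
  const int n1 = x1.nrow(), n2 = x2.nrow(), p = x1.ncol();
  if (x2.ncol() != p) stop("feature dimension mismatch");
  NumericMatrix K(n1, n2);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      double d2 = 0.0;
      for (int f = 0; f < p; ++f) {
        const double d = x1(i, f) - x2(j, f);
        d2 += d * d;
      }
      K(i, j) = std::exp(-sigma * d2);
    }
  }
  return K;
}

// Two-variable SMO for the C-SVM dual with maximal-violating-pair working-set
// selection (Keerthi et al.):
//   max  sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K_ij
//   s.t. 0 <= alpha_i <= C,  sum_i alpha_i y_i = 0.
// K is the full training kernel matrix; y in {-1, +1}.
// Returns alpha, bias b, dual objective, iterations, and the achieved
// KKT-violation gap.
// [[Rcpp::export(name = ".smoTrainCpp")]]
List smoTrainCpp(NumericMatrix K, NumericVector y, double C, double eps,
                 int maxIter) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("label length must match kernel size");

  std::vector<double> alpha(n, 0.0);
  // g[t] = sum_j alpha_j y_j K_tj (decision value without bias)
  std::vector<double> g(n, 0.0);

  int iter = 0;
  double gap = std::numeric_limits<double>::infinity();
  // bound membership uses a tolerance: clipped steps can leave an alpha a
  // rounding error away from 0 or C, and exact comparisons would then
  // reselect the same zero-progress pair forever
  const double tolA = 1e-12 * C;
  auto atLower = [&](int t) { return alpha[t] <= tolA; };
  auto atUpper = [&](int t) { return alpha[t] >= C - tolA; };

  while (iter < maxIter) {
    // first-order selection of i, second-order selection of j (LIBSVM WSS2):
    // j maximizes the guaranteed objective decrease, which avoids zero-length
    // clipped steps that stall the maximal-violating-pair rule.
    int i = -1, j = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = y[t] - g[t];  // -E_t = -y_t * grad_t
      const bool up = (y[t] > 0) ? !atUpper(t) : !atLower(t);
      if (up && v > gmax) { gmax = v; i = t; }
    }
    double bestDec = 0.0;
    for (int t = 0; t < n; ++t) {
      const double v = y[t] - g[t];
      const bool lo = (y[t] > 0) ? !atLower(t) : !atUpper(t);
      if (!lo) continue;
      if (v < gmin) gmin = v;
      if (i >= 0 && v < gmax) {
        double a = K(i, i) + K(t, t) - 2.0 * K(i, t);
        if (a <= 0) a = 1e-12;
        const double bdiff = gmax - v;
        const double dec = bdiff * bdiff / a;
        if (j < 0 || dec > bestDec) { bestDec = dec; j = t; }
      }
    }
    gap = gmax - gmin;
    if (i < 0 || j < 0 || gap <= eps) break;

    // analytic two-variable step
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 0) eta = 1e-12;
    const double Ei = g[i] - y[i];
    const double Ej = g[j] - y[j];
    double L, H;
    const double ai = alpha[i], aj = alpha[j];
    if (y[i] != y[j]) {
      L = std::max(0.0, aj - ai);
      H = std::min(C, C + aj - ai);
    } else {
      L = std::max(0.0, ai + aj - C);
      H = std::min(C, ai + aj);
    }
    double ajNew = aj + y[j] * (Ei - Ej) / eta;
    if (ajNew > H) ajNew = H;
    if (ajNew < L) ajNew = L;
    const double aiNew = ai + y[i] * y[j] * (aj - ajNew);
    const double di = aiNew - ai, dj = ajNew - aj;
    if (std::fabs(dj) < 1e-16 && std::fabs(di) < 1e-16) break;
    alpha[i] = aiNew;
    alpha[j] = ajNew;
    for (int t = 0; t < n; ++t)
      g[t] += di * y[i] * K(t, i) + dj * y[j] * K(t, j);
    ++iter;
  }

  // bias from the midpoint of the violating interval (exact for margin SVs)
  double gmax = -std::numeric_limits<double>::infinity();
  double gmin = std::numeric_limits<double>::infinity();
  for (int t = 0; t < n; ++t) {
    const double v = y[t] - g[t];
    const bool up = (y[t] > 0) ? !atUpper(t) : !atLower(t);
    const bool lo = (y[t] > 0) ? !atLower(t) : !atUpper(t);
    if (up && v > gmax) gmax = v;
    if (lo && v < gmin) gmin = v;
  }
  double b;
  if (R_finite(gmax) && R_finite(gmin)) b = 0.5 * (gmax + gmin);
  else if (R_finite(gmax)) b = gmax;
  else b = gmin;

  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (1.0 - 0.5 * y[t] * g[t]);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["objective"] = obj, _["iterations"] = iter,
                      _["gap"] = gap);
}
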