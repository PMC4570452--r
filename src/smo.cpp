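#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-margin C-SVC dual solved by SMO with maximal-violating-pair working
// set selection (Keerthi's b_up / b_low criterion). Deterministic: no
// shrinking, no randomised ordering; ties resolved by lowest index.
//
// X: n x d matrix (already scaled), y in {-1,+1}.
// kernel: 0 = linear (x.x'), 1 = RBF exp(-gamma * ||x-x'||^2).
// Returns alpha, bias b, iteration count and convergence flag.
// [[Rcpp::export]]
List smo_cpp(NumericMatrix X, IntegerVector y, int kernel, double gamma,
             double C, double tol, int max_iter) {
  int n = X.nrow(), d = X.ncol();

  // precomputed kernel matrix (n is a few hundred at most)
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double k;
      if (kernel == 0) {
        k = 0.0;
        for (int c = 0; c < d; ++c) k += X(i, c) * X(j, c);
      } else {
        double s = 0.0;
        for (int c = 0; c < d; ++c) {
          double t = X(i, c) - X(j, c);
          s += t * t;
        }
        k = std::exp(-gamma * s);
      }
      K[(size_t)i * n + j] = k;
      K[(size_t)j * n + i] = k;
    }
  }

  std::vector<double> alpha(n, 0.0);
  // F_i = sum_j alpha_j y_j K_ij - y_i  (decision value without bias, minus target)
  std::vector<double> F(n);
  for (int i = 0; i < n; ++i) F[i] = -(double)y[i];

  int iter = 0;
  bool converged = false;
  double b_up = 0.0, b_low = 0.0;

  while (iter < max_iter) {
    // I_up:  y=+1 & alpha<C  or y=-1 & alpha>0   (F can still decrease b_up)
    // I_low: y=+1 & alpha>0  or y=-1 & alpha<C
    int i_up = -1, i_low = -1;
    b_up = R_PosInf;
    b_low = R_NegInf;
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool in_low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (in_up && F[t] < b_up) { b_up = F[t]; i_up = t; }
      if (in_low && F[t] > b_low) { b_low = F[t]; i_low = t; }
    }
    if (i_up < 0 || i_low < 0 || b_low - b_up < tol) {
      converged = (i_up >= 0 && i_low >= 0);
      break;
    }

    int i = i_low, j = i_up;  // update pair (most violating)
    double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
           Kij = K[(size_t)i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 0) eta = 1e-12;

    double ai = alpha[i], aj = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj - ai);
      H = std::min(C, C + aj - ai);
    } else {
      L = std::max(0.0, ai + aj - C);
      H = std::min(C, ai + aj);
    }
    double aj_new = aj + y[j] * (F[i] - F[j]) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = ai + y[i] * y[j] * (aj - aj_new);

    // snap to the box so near-bound alphas leave the working sets instead
    // of being re-selected with zero-progress steps
    double eps_b = 1e-10 * C;
    if (ai_new < eps_b) ai_new = 0.0; else if (ai_new > C - eps_b) ai_new = C;
    if (aj_new < eps_b) aj_new = 0.0; else if (aj_new > C - eps_b) aj_new = C;

    double di = (ai_new - ai) * y[i], dj = (aj_new - aj) * y[j];
    if (di == 0.0 && dj == 0.0) {
      // maximal violating pair cannot move at numerical precision
      converged = true;
      break;
    }
    alpha[i] = ai_new;
    alpha[j] = aj_new;
    for (int t = 0; t < n; ++t)
      F[t] += di * K[(size_t)i * n + t] + dj * K[(size_t)j * n + t];
    ++iter;
  }

  // bias: average over free support vectors, else midpoint of the bounds
  double bsum = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      bsum += -F[t];  // free SV: sum_j alpha_j y_j K_tj + b = y_t
      ++nfree;
    }
  }
  double b = nfree > 0 ? bsum / nfree : -(b_up + b_low) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged);
}
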