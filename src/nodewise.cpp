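// Coordinate-descent solver for L1-penalised nodewise regression on a
// standardized weighted Gram matrix. One Gram matrix per cell line is
// computed in R (BLAS crossprod); the per-target lasso paths run here.
//
// Problem, per target gene l (standardized scale, C has unit diagonal):
//   min_b 0.5 * b' C[-l,-l] b - C[l,-l]' b + lambda * ||b||_1
// solved over a decreasing lambda path with warm starts. The gradient
// g_j = c_j - sum_k C[j,k] b_k is maintained incrementally.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Path for one target; b (length p, b[l] fixed at 0) is warm-started across
// lambdas. Fills sig2[k] = 1 - c'b - b'g (weighted residual variance of the
// standardized target) and df[k] = number of active coefficients.
static void cd_path(const double* C, int p, int l,
                    const std::vector<double>& lambdas,
                    double* b, double* g,
                    double* sig2, int* df,
                    int maxit, double tol) {
  const double* Cl = C + (size_t)l * p; // column l: c_j = C[j, l]
  for (int j = 0; j < p; ++j) { b[j] = 0.0; g[j] = Cl[j]; }
  const int K = (int)lambdas.size();
  std::vector<int> active;
  active.reserve(p);
  for (int k = 0; k < K; ++k) {
    const double lam = lambdas[k];
    // full sweeps establish the active set; inner sweeps iterate it
    for (int outer = 0; outer < maxit; ++outer) {
      double maxdelta = 0.0;
      active.clear();
      for (int j = 0; j < p; ++j) {
        if (j == l) continue;
        const double bj_old = b[j];
        const double z = g[j] + bj_old;      // C[j,j] == 1
        const double bj_new = soft_threshold(z, lam);
        const double delta = bj_new - bj_old;
        if (delta != 0.0) {
          const double* Cj = C + (size_t)j * p;
          for (int t = 0; t < p; ++t) g[t] -= delta * Cj[t];
          b[j] = bj_new;
          const double ad = std::fabs(delta);
          if (ad > maxdelta) maxdelta = ad;
        }
        if (b[j] != 0.0) active.push_back(j);
      }
      if (maxdelta < tol) break;
      for (int inner = 0; inner < maxit; ++inner) {
        double md = 0.0;
        for (int a = 0; a < (int)active.size(); ++a) {
          const int j = active[a];
          const double bj_old = b[j];
          const double bj_new = soft_threshold(g[j] + bj_old, lam);
          const double delta = bj_new - bj_old;
          if (delta != 0.0) {
            const double* Cj = C + (size_t)j * p;
            for (int t = 0; t < p; ++t) g[t] -= delta * Cj[t];
            b[j] = bj_new;
            const double ad = std::fabs(delta);
            if (ad > md) md = ad;
          }
        }
        if (md < tol) break;
      }
    }
    double cb = 0.0, bg = 0.0;
    int nact = 0;
    for (int j = 0; j < p; ++j) {
      if (j == l) continue;
      if (b[j] != 0.0) {
        ++nact;
        cb += Cl[j] * b[j];
        bg += b[j] * g[j];
      }
    }
    double s2 = 1.0 - cb - bg;
    if (s2 < 0.0) s2 = 0.0;
    sig2[k] = s2;
    df[k] = nact;
  }
}

// Lasso paths for every target gene of one cell line.
// C: p x p standardized weighted Gram (unit diagonal); lambdas: decreasing.
// Returns sig2 (K x p), df (K x p) and, when keep_beta, the coefficient
// matrix at the smallest lambda: beta(l, j) = coefficient of predictor j in
// the regression of target l (standardized scale, zero diagonal).
// [[Rcpp::export]]
List cpp_nodewise(NumericMatrix C, NumericVector lambdas,
                  bool keep_beta = false,
                  int maxit = 1000, double tol = 1e-7) {
  const int p = C.nrow();
  const int K = lambdas.size();
  if (C.ncol() != p) stop("C must be square");
  if (K < 1) stop("need at least one lambda");
  std::vector<double> lam(lambdas.begin(), lambdas.end());
  for (int k = 1; k < K; ++k)
    if (lam[k] > lam[k - 1]) stop("lambdas must be non-increasing");

  NumericMatrix sig2(K, p), beta;
  IntegerMatrix df(K, p);
  if (keep_beta) beta = NumericMatrix(p, p);
  std::vector<double> b(p), g(p);
  std::vector<double> s2(K);
  std::vector<int> nact(K);
  const double* Cp = REAL(C);

  for (int l = 0; l < p; ++l) {
    cd_path(Cp, p, l, lam, b.data(), g.data(), s2.data(), nact.data(),
            maxit, tol);
    for (int k = 0; k < K; ++k) { sig2(k, l) = s2[k]; df(k, l) = nact[k]; }
    if (keep_beta)
      for (int j = 0; j < p; ++j) beta(l, j) = (j == l) ? 0.0 : b[j];
  }
  if (keep_beta)
    return List::create(_["sigma2"] = sig2, _["df"] = df, _["beta"] = beta);
  return List::create(_["sigma2"] = sig2, _["df"] = df);
}

// Single-target lasso path; returns the coefficient vector at the smallest
// lambda plus the per-lambda residual variances and dfs.
// [[Rcpp::export]]
List cpp_lasso_single(NumericMatrix C, int target, NumericVector lambdas,
                      int maxit = 1000, double tol = 1e-7) {
  const int p = C.nrow();
  if (target < 1 || target > p) stop("target out of range");
  const int K = lambdas.size();
  std::vector<double> lam(lambdas.begin(), lambdas.end());
  std::vector<double> b(p), g(p), s2(K);
  std::vector<int> nact(K);
  cd_path(REAL(C), p, target - 1, lam, b.data(), g.data(), s2.data(),
          nact.data(), maxit, tol);
  return List::create(_["beta"] = NumericVector(b.begin(), b.end()),
                      _["sigma2"] = NumericVector(s2.begin(), s2.end()),
                      _["df"] = IntegerVector(nact.begin(), nact.end()));
}
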