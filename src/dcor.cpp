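#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Distance-correlation kernels (Szekely V-statistic).  All matrices are
// T x T pairwise-distance matrices stored column-major in std::vector.

// Squared Euclidean distances between rows of X (T x p).
static std::vector<double> row_sqdist(const NumericMatrix& X) {
  const int T = X.nrow(), p = X.ncol();
  std::vector<double> D((size_t)T * T, 0.0);
  for (int j = 0; j < T; ++j) {
    for (int k = j + 1; k < T; ++k) {
      double s = 0.0;
      for (int v = 0; v < p; ++v) {
        const double d = X(j, v) - X(k, v);
        s += d * d;
      }
      D[(size_t)j + (size_t)T * k] = s;
      D[(size_t)k + (size_t)T * j] = s;
    }
  }
  return D;
}

// Double-center a symmetric distance matrix in place:
// A_jk <- a_jk - rowmean_j - colmean_k + grandmean.
static void double_center(std::vector<double>& A, int T) {
  std::vector<double> rm(T, 0.0);
  double g = 0.0;
  for (int k = 0; k < T; ++k) {
    double s = 0.0;
    const double* col = A.data() + (size_t)T * k;
    for (int j = 0; j < T; ++j) s += col[j];
    rm[k] = s / T;
    g += s;
  }
  g /= (double)T * T;
  for (int k = 0; k < T; ++k) {
    double* col = A.data() + (size_t)T * k;
    for (int j = 0; j < T; ++j) col[j] += g - rm[j] - rm[k];
  }
}

// dCor from two already-centered matrices.
static double dcor_centered(const std::vector<double>& A,
                            const std::vector<double>& B, int T) {
  double sab = 0.0, saa = 0.0, sbb = 0.0;
  const size_t n = (size_t)T * T;
  for (size_t i = 0; i < n; ++i) {
    sab += A[i] * B[i];
    saa += A[i] * A[i];
    sbb += B[i] * B[i];
  }
  if (saa <= 0.0 || sbb <= 0.0) return 0.0;
  const double r2 = sab / std::sqrt(saa * sbb);
  return r2 > 0.0 ? std::sqrt(r2) : 0.0;
}

static void sqrt_all(std::vector<double>& D) {
  for (size_t i = 0; i < D.size(); ++i) D[i] = std::sqrt(D[i]);
}

// [[Rcpp::export]]
double cpp_dcor(const NumericMatrix& X, const NumericMatrix& Y) {
  const int T = X.nrow();
  std::vector<double> A = row_sqdist(X), B = row_sqdist(Y);
  sqrt_all(A);
  sqrt_all(B);
  double_center(A, T);
  double_center(B, T);
  return dcor_centered(A, B, T);
}

// Within-network similarity, set-based reading: mean over voxels v of
// dCor(column v, remaining columns as one multivariate sample).  The
// complement's squared distances are the full-block squared distances minus
// the voxel's own squared contribution, so the full matrix is computed once.
// [[Rcpp::export]]
double cpp_within_set(const NumericMatrix& B) {
  const int T = B.nrow(), k = B.ncol();
  const std::vector<double> D2 = row_sqdist(B);
  std::vector<double> a((size_t)T * T), b((size_t)T * T);
  double acc = 0.0;
  for (int v = 0; v < k; ++v) {
    for (int j = 0; j < T; ++j) {
      for (int m = 0; m < T; ++m) {
        const double d = B(j, v) - B(m, v);
        const double s2 = d * d;
        a[(size_t)j + (size_t)T * m] = std::fabs(d);
        double rest = D2[(size_t)j + (size_t)T * m] - s2;
        if (rest < 0.0) rest = 0.0;
        b[(size_t)j + (size_t)T * m] = std::sqrt(rest);
      }
    }
    double_center(a, T);
    double_center(b, T);
    acc += dcor_centered(a, b, T);
  }
  return acc / k;
}

// Within-network similarity, pairwise reading: mean over unordered voxel
// pairs of the univariate dCor.  Exposed behind a config switch only.
// [[Rcpp::export]]
double cpp_within_pairwise(const NumericMatrix& B) {
  const int T = B.nrow(), k = B.ncol();
  std::vector<std::vector<double>> cent(k);
  for (int v = 0; v < k; ++v) {
    std::vector<double> a((size_t)T * T);
    for (int j = 0; j < T; ++j)
      for (int m = 0; m < T; ++m)
        a[(size_t)j + (size_t)T * m] = std::fabs(B(j, v) - B(m, v));
    double_center(a, T);
    cent[v] = std::move(a);
  }
  double acc = 0.0;
  long npair = 0;
  for (int u = 0; u < k; ++u)
    for (int v = u + 1; v < k; ++v) {
      acc += dcor_centered(cent[u], cent[v], T);
      ++npair;
    }
  return acc / (double)npair;
}

// All pairwise between-network dCor values plus within-network similarities
// for a list of T x k_i blocks; each block's centered distance matrix is
// computed once and reused across pairs.
// [[Rcpp::export]]
List cpp_connectome(const List& blocks, bool pairwise_within) {
  const int n = blocks.size();
  std::vector<std::vector<double>> cent(n);
  int T = 0;
  for (int i = 0; i < n; ++i) {
    NumericMatrix Bi = blocks[i];
    T = Bi.nrow();
    std::vector<double> A = row_sqdist(Bi);
    sqrt_all(A);
    double_center(A, T);
    cent[i] = std::move(A);
  }
  NumericMatrix between(n, n);
  NumericVector within(n);
  for (int i = 0; i < n; ++i) {
    between(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double d = dcor_centered(cent[i], cent[j], T);
      between(i, j) = d;
      between(j, i) = d;
    }
    NumericMatrix Bi = blocks[i];
    within[i] = pairwise_within ? cpp_within_pairwise(Bi) : cpp_within_set(Bi);
  }
  return List::create(_["between"] = between, _["within"] = within);
}
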