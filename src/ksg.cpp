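#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov-Stogbauer-Grassberger mutual information, variant I(1):
//   MI = psi(k) + psi(N) - < psi(n_x + 1) + psi(n_y + 1) >
// where eps_i is the max-norm distance in the joint space to the k-th
// nearest neighbour of point i (self excluded) and n_x, n_y count the
// points strictly within eps_i along each marginal. Returned in nats,
// unclipped (may be slightly negative for weakly dependent samples).
// [[Rcpp::export]]
double ksg_mi_cpp(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow();
  if (y.nrow() != n) stop("x and y must have the same number of rows");
  if (k < 1 || k >= n) stop("need 1 <= k < n");
  const int dx_cols = x.ncol(), dy_cols = y.ncol();
  const double* xp = REAL(x);
  const double* yp = REAL(y);

  std::vector<double> dx(n), dy(n), tmp(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    // marginal max-norm distances from point i
    {
      const double xi0 = xp[i];
      for (int j = 0; j < n; ++j) dx[j] = std::fabs(xp[j] - xi0);
      for (int c = 1; c < dx_cols; ++c) {
        const double* col = xp + (size_t)c * n;
        const double xic = col[i];
        for (int j = 0; j < n; ++j) {
          double v = std::fabs(col[j] - xic);
          if (v > dx[j]) dx[j] = v;
        }
      }
      const double yi0 = yp[i];
      for (int j = 0; j < n; ++j) dy[j] = std::fabs(yp[j] - yi0);
      for (int c = 1; c < dy_cols; ++c) {
        const double* col = yp + (size_t)c * n;
        const double yic = col[i];
        for (int j = 0; j < n; ++j) {
          double v = std::fabs(col[j] - yic);
          if (v > dy[j]) dy[j] = v;
        }
      }
    }
    for (int j = 0; j < n; ++j) tmp[j] = dx[j] > dy[j] ? dx[j] : dy[j];
    tmp[i] = R_PosInf; // exclude self
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      nx += dx[j] < eps;
      ny += dy[j] < eps;
    }
    // the self point (distance 0) was counted in both
    acc += R::digamma((double)nx) + R::digamma((double)ny);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}
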