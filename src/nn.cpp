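#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimal 2-d k-d tree over anchor points, stored as a median-ordered index
// vector (node = middle of its range). Only min-distance queries are needed.

namespace {

struct KD {
  const double* x;
  const double* y;
  std::vector<int> id;

  void build(int lo, int hi, int axis) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    const double* key = axis ? y : x;
    std::nth_element(id.begin() + lo, id.begin() + mid, id.begin() + hi,
                     [key](int a, int b) { return key[a] < key[b]; });
    build(lo, mid, 1 - axis);
    build(mid + 1, hi, 1 - axis);
  }

  void query(int lo, int hi, int axis, double qx, double qy, double& best) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2;
    int p = id[mid];
    double dx = qx - x[p], dy = qy - y[p];
    double d2 = dx * dx + dy * dy;
    if (d2 < best) best = d2;
    double diff = axis ? (qy - y[p]) : (qx - x[p]);
    int nlo, nhi, flo, fhi;
    if (diff <= 0) { nlo = lo; nhi = mid; flo = mid + 1; fhi = hi; }
    else           { nlo = mid + 1; nhi = hi; flo = lo; fhi = mid; }
    query(nlo, nhi, 1 - axis, qx, qy, best);
    if (diff * diff < best) query(flo, fhi, 1 - axis, qx, qy, best);
  }
};

} // namespace

// [[Rcpp::export(name = ".nn_min_dist_kd")]]
NumericVector nn_min_dist_kd(NumericVector ax, NumericVector ay,
                             NumericVector qx, NumericVector qy) {
  const int n = ax.size(), m = qx.size();
  if (n == 0) stop("no anchor points");
  if (ay.size() != n || qy.size() != m) stop("coordinate length mismatch");
  KD tree;
  tree.x = ax.begin();
  tree.y = ay.begin();
  tree.id.resize(n);
  for (int i = 0; i < n; ++i) tree.id[i] = i;
  tree.build(0, n, 0);
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double best = R_PosInf;
    tree.query(0, n, 0, qx[j], qy[j], best);
    out[j] = std::sqrt(best);
  }
  return out;
}
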