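#include <Rcpp.h>
#include <vector>
#include <algorithm>

// 3-D KD-tree nearest-neighbour search over target points.
//
// Tie-breaking contract: among equidistant target points the one with the
// lowest original index wins, matching which.min() in the brute-force R
// oracle. Subtree pruning is therefore strict (dist > best, not >=), so an
// equal-distance candidate with a lower index is never pruned away, and the
// squared distance is accumulated in the same operation order as the R
// expression (dx^2 + dy^2) + dz^2 so both paths produce bit-identical
// doubles.

namespace {

struct KDTree {
  const double *x, *y, *z;  // column pointers into the target matrix
  int n;
  std::vector<int> perm;    // perm[node range] -> original 0-based index
  // implicit balanced tree over perm via nth_element; axis = depth % 3

  double coord(int i, int axis) const {
    return axis == 0 ? x[i] : (axis == 1 ? y[i] : z[i]);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int axis = depth % 3;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&](int a, int b) {
                       double ca = coord(a, axis), cb = coord(b, axis);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(double qx, double qy, double qz, int lo, int hi, int depth,
             double &best, int &bestIdx) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2;
    int i = perm[mid];
    double dx = x[i] - qx, dy = y[i] - qy, dz = z[i] - qz;
    double d2 = (dx * dx + dy * dy) + dz * dz;
    if (d2 < best || (d2 == best && i < bestIdx)) {
      best = d2;
      bestIdx = i;
    }
    int axis = depth % 3;
    double q = axis == 0 ? qx : (axis == 1 ? qy : qz);
    double diff = q - coord(i, axis);
    int nearLo, nearHi, farLo, farHi;
    if (diff < 0) {
      nearLo = lo; nearHi = mid; farLo = mid + 1; farHi = hi;
    } else {
      nearLo = mid + 1; nearHi = hi; farLo = lo; farHi = mid;
    }
    query(qx, qy, qz, nearLo, nearHi, depth + 1, best, bestIdx);
    if (diff * diff <= best)  // equal distance must still be explored
      query(qx, qy, qz, farLo, farHi, depth + 1, best, bestIdx);
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_nearest_points(Rcpp::NumericMatrix query,
                              Rcpp::NumericMatrix target) {
  int nq = query.nrow(), nt = target.nrow();
  if (nt == 0) Rcpp::stop("target point set is empty");
  KDTree tree;
  tree.x = &target(0, 0);
  tree.y = &target(0, 1);
  tree.z = &target(0, 2);
  tree.n = nt;
  tree.perm.resize(nt);
  for (int i = 0; i < nt; ++i) tree.perm[i] = i;
  tree.build(0, nt, 0);

  Rcpp::IntegerVector index(nq);
  Rcpp::NumericVector dist(nq);
  for (int q = 0; q < nq; ++q) {
    double best = R_PosInf;
    int bestIdx = nt;
    tree.query(query(q, 0), query(q, 1), query(q, 2), 0, nt, 0, best, bestIdx);
    index[q] = bestIdx + 1;  // 1-based for R
    dist[q] = std::sqrt(best);
  }
  return Rcpp::List::create(Rcpp::Named("index") = index,
                            Rcpp::Named("distance") = dist);
}
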