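#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Lightweight 3-d kd-tree over the reference cloud. Built per call; query
// cost O(log M) expected. Ties between equidistant reference points are
// broken toward the lowest index so results match the brute-force scan
// exactly.

namespace {

struct KdNode {
  int idx;        // point index at this node
  int left, right;
  int axis;
};

struct KdTree {
  const double* pts; // column-major M x 3
  int m;
  std::vector<KdNode> nodes;
  int root;

  double coord(int i, int axis) const { return pts[axis * m + i]; }

  int build(std::vector<int>& ids, int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int axis = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(ids.begin() + lo, ids.begin() + mid, ids.begin() + hi,
                     [&](int a, int b) {
                       double ca = coord(a, axis), cb = coord(b, axis);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    int node_id = (int)nodes.size();
    nodes.push_back(KdNode());
    nodes[node_id].idx = ids[mid];
    nodes[node_id].axis = axis;
    int l = build(ids, lo, mid, depth + 1);
    int r = build(ids, mid + 1, hi, depth + 1);
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }

  void init(const double* p, int m_) {
    pts = p; m = m_;
    nodes.clear();
    nodes.reserve(m);
    std::vector<int> ids(m);
    for (int i = 0; i < m; ++i) ids[i] = i;
    root = build(ids, 0, m, 0);
  }

  void query(const double* q, int node_id, int& best, double& best_d2) const {
    if (node_id < 0) return;
    const KdNode& nd = nodes[node_id];
    double dx = q[0] - coord(nd.idx, 0);
    double dy = q[1] - coord(nd.idx, 1);
    double dz = q[2] - coord(nd.idx, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best_d2 || (d2 == best_d2 && nd.idx < best)) {
      best_d2 = d2;
      best = nd.idx;
    }
    double diff = q[nd.axis] - coord(nd.idx, nd.axis);
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    query(q, near, best, best_d2);
    if (diff * diff <= best_d2) query(q, far, best, best_d2);
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_nn_kdtree")]]
List cpp_nn_kdtree(NumericMatrix query, NumericMatrix reference) {
  int n = query.nrow(), m = reference.nrow();
  KdTree tree;
  tree.init(REAL(reference), m);
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = { query(i, 0), query(i, 1), query(i, 2) };
    int best = m; // larger than any index so ties resolve to lowest real index
    double best_d2 = std::numeric_limits<double>::infinity();
    tree.query(q, tree.root, best, best_d2);
    idx[i] = best + 1; // 1-based for R
    dist[i] = std::sqrt(best_d2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// [[Rcpp::export(name = ".cpp_nn_brute")]]
List cpp_nn_brute(NumericMatrix query, NumericMatrix reference) {
  int n = query.nrow(), m = reference.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int best = -1;
    double best_d2 = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      double dx = qx - reference(j, 0);
      double dy = qy - reference(j, 1);
      double dz = qz - reference(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best_d2) { best_d2 = d2; best = j; }
    }
    idx[i] = best + 1;
    dist[i] = std::sqrt(best_d2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Score rigid-transform candidates by inlier votes against a fixed target:
// one tree build, many candidates.
// [[Rcpp::export(name = ".cpp_score_candidates")]]
IntegerVector cpp_score_candidates(NumericMatrix query, NumericMatrix reference,
                                   List rotations, NumericMatrix translations,
                                   double tol) {
  int m = reference.nrow();
  KdTree tree;
  tree.init(REAL(reference), m);
  int nc = rotations.size();
  int n = query.nrow();
  double tol2 = tol * tol;
  IntegerVector votes(nc);
  for (int c = 0; c < nc; ++c) {
    NumericMatrix R = rotations[c];
    double tx = translations(c, 0), ty = translations(c, 1),
           tz = translations(c, 2);
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      double x = query(i, 0), y = query(i, 1), z = query(i, 2);
      double q[3] = {
        R(0, 0) * x + R(0, 1) * y + R(0, 2) * z + tx,
        R(1, 0) * x + R(1, 1) * y + R(1, 2) * z + ty,
        R(2, 0) * x + R(2, 1) * y + R(2, 2) * z + tz
      };
      int best = m;
      double best_d2 = std::numeric_limits<double>::infinity();
      tree.query(q, tree.root, best, best_d2);
      if (best_d2 <= tol2) ++cnt;
    }
    votes[c] = cnt;
  }
  return votes;
}
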