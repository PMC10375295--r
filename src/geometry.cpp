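#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Implicit balanced 3-d tree: idx[] is permuted so that for any node range
// [lo, hi) at depth d the median element sits at (lo+hi)/2 and partitions the
// range along axis d % 3. No per-node storage is needed; searches recurse on
// the same ranges.
namespace {

struct KdTree {
  const double* x; // column-major N x 3
  int n;
  std::vector<int> idx;

  KdTree(const NumericMatrix& pts) : x(pts.begin()), n(pts.nrow()), idx(pts.nrow()) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    build(0, n, 0);
  }
  inline double coord(int i, int axis) const { return x[axis * (size_t)n + i]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int axis = depth % 3;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, axis) < coord(b, axis); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  inline double dist2(int i, const double* q) const {
    double dx = coord(i, 0) - q[0], dy = coord(i, 1) - q[1], dz = coord(i, 2) - q[2];
    return dx * dx + dy * dy + dz * dz;
  }

  void radius(const double* q, double r2, double r, int lo, int hi, int depth,
              std::vector<int>& out) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2;
    int axis = depth % 3;
    int p = idx[mid];
    if (dist2(p, q) <= r2) out.push_back(p);
    double diff = q[axis] - coord(p, axis);
    if (diff <= 0) {
      radius(q, r2, r, lo, mid, depth + 1, out);
      if (-diff <= r) radius(q, r2, r, mid + 1, hi, depth + 1, out);
    } else {
      radius(q, r2, r, mid + 1, hi, depth + 1, out);
      if (diff <= r) radius(q, r2, r, lo, mid, depth + 1, out);
    }
  }

  // k nearest neighbours of q, excluding index `self` (-1 to keep all).
  // Ties in distance break toward the lower point index.
  void knn(const double* q, int k, int self,
           std::vector<std::pair<double, int> >& heap) const {
    heap.clear();
    knn_rec(q, k, self, 0, n, 0, heap);
    std::sort(heap.begin(), heap.end());
  }

 private:
  void knn_rec(const double* q, int k, int self, int lo, int hi, int depth,
               std::vector<std::pair<double, int> >& heap) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2;
    int axis = depth % 3;
    int p = idx[mid];
    if (p != self) {
      std::pair<double, int> cand(dist2(p, q), p);
      if ((int)heap.size() < k) {
        heap.push_back(cand);
        std::push_heap(heap.begin(), heap.end());
      } else if (cand < heap.front()) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = cand;
        std::push_heap(heap.begin(), heap.end());
      }
    }
    double diff = q[axis] - coord(p, axis);
    int near_lo = diff <= 0 ? lo : mid + 1, near_hi = diff <= 0 ? mid : hi;
    int far_lo = diff <= 0 ? mid + 1 : lo, far_hi = diff <= 0 ? hi : mid;
    knn_rec(q, k, self, near_lo, near_hi, depth + 1, heap);
    double worst = ((int)heap.size() < k) ? R_PosInf : heap.front().first;
    if (diff * diff <= worst) knn_rec(q, k, self, far_lo, far_hi, depth + 1, heap);
  }
};

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_knn_graph(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  KdTree tree(pts);
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > heap;
  heap.reserve(k + 1);
  for (int i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    tree.knn(q, k, i, heap);
    for (int j = 0; j < k; ++j) out(i, j) = heap[j].second + 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_radius_search(NumericMatrix pts, NumericMatrix queries, double r) {
  if (r <= 0) stop("radius must be positive");
  KdTree tree(pts);
  int m = queries.nrow();
  List out(m);
  std::vector<int> hits;
  for (int i = 0; i < m; ++i) {
    hits.clear();
    double q[3] = {queries(i, 0), queries(i, 1), queries(i, 2)};
    tree.radius(q, r * r, r, 0, pts.nrow(), 0, hits);
    std::sort(hits.begin(), hits.end());
    IntegerVector v(hits.size());
    for (size_t j = 0; j < hits.size(); ++j) v[j] = hits[j] + 1;
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_radius_union(NumericMatrix pts, NumericMatrix queries, double r) {
  if (r <= 0) stop("radius must be positive");
  KdTree tree(pts);
  int n = pts.nrow(), m = queries.nrow();
  std::vector<char> seen(n, 0);
  std::vector<int> hits;
  for (int i = 0; i < m; ++i) {
    hits.clear();
    double q[3] = {queries(i, 0), queries(i, 1), queries(i, 2)};
    tree.radius(q, r * r, r, 0, n, 0, hits);
    for (size_t j = 0; j < hits.size(); ++j) seen[hits[j]] = 1;
  }
  std::vector<int> out;
  for (int i = 0; i < n; ++i)
    if (seen[i]) out.push_back(i + 1);
  return wrap(out);
}

// Connected components of the <= tol proximity graph, grown breadth-first
// with kd-tree radius queries. Component ids are assigned in order of the
// lowest point index they contain.
// [[Rcpp::export]]
IntegerVector cpp_euclidean_cluster(NumericMatrix pts, double tol) {
  if (tol <= 0) stop("tolerance must be positive");
  int n = pts.nrow();
  KdTree tree(pts);
  IntegerVector comp(n, 0);
  std::vector<int> stack, hits;
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    if (comp[i] != 0) continue;
    ++next_id;
    comp[i] = next_id;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      hits.clear();
      double q[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
      tree.radius(q, tol * tol, tol, 0, n, 0, hits);
      for (size_t j = 0; j < hits.size(); ++j) {
        int h = hits[j];
        if (comp[h] == 0) {
          comp[h] = next_id;
          stack.push_back(h);
        }
      }
    }
  }
  return comp;
}

// Farthest-point sampling: greedy max-min selection starting from `start`
// (1-based). Ties break toward the lower index.
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix pts, int target_n, int start) {
  int n = pts.nrow();
  if (target_n > n) stop("target_n exceeds the number of points");
  if (start < 1 || start > n) stop("start index out of range");
  IntegerVector out(target_n);
  std::vector<double> best(n, R_PosInf);
  int cur = start - 1;
  out[0] = cur + 1;
  for (int s = 1; s < target_n; ++s) {
    double cx = pts(cur, 0), cy = pts(cur, 1), cz = pts(cur, 2);
    int far_i = -1;
    double far_d = -1.0;
    for (int i = 0; i < n; ++i) {
      double dx = pts(i, 0) - cx, dy = pts(i, 1) - cy, dz = pts(i, 2) - cz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best[i]) best[i] = d;
      if (best[i] > far_d) {
        far_d = best[i];
        far_i = i;
      }
    }
    cur = far_i;
    out[s] = cur + 1;
  }
  return out;
}

// One RANSAC pass for a 2-point line hypothesis. Hypotheses are scored by
// the number of points within `score_thresh` of the line (a tight core band
// favours a pod's axis over the bisector of two crossing pods); the full
// consensus at `thresh` is recomputed by the caller. Uses R's RNG so results
// follow set.seed(). Returns the winning sample pair (1-based) and its score.
// [[Rcpp::export]]
List cpp_ransac_line(NumericMatrix pts, int iters, double thresh,
                     double score_thresh) {
  int m = pts.nrow();
  if (m < 2) stop("need at least two points");
  double t2 = score_thresh * score_thresh;
  (void)thresh;
  int best_count = -1, best_i = 0, best_j = 1;
  for (int it = 0; it < iters; ++it) {
    int i = 0, j = 0;
    double dx = 0, dy = 0, dz = 0, len2 = 0;
    int tries = 0;
    do { // resample degenerate (coincident) pairs
      i = (int)(unif_rand() * m);
      j = (int)(unif_rand() * m);
      if (i >= m) i = m - 1;
      if (j >= m) j = m - 1;
      dx = pts(j, 0) - pts(i, 0);
      dy = pts(j, 1) - pts(i, 1);
      dz = pts(j, 2) - pts(i, 2);
      len2 = dx * dx + dy * dy + dz * dz;
    } while (len2 < 1e-24 && ++tries < 100);
    if (len2 < 1e-24) continue;
    double inv = 1.0 / std::sqrt(len2);
    dx *= inv; dy *= inv; dz *= inv;
    double ax = pts(i, 0), ay = pts(i, 1), az = pts(i, 2);
    int count = 0;
    for (int p = 0; p < m; ++p) {
      double px = pts(p, 0) - ax, py = pts(p, 1) - ay, pz = pts(p, 2) - az;
      double t = px * dx + py * dy + pz * dz;
      double rx = px - t * dx, ry = py - t * dy, rz = pz - t * dz;
      if (rx * rx + ry * ry + rz * rz <= t2) ++count;
    }
    if (count > best_count) {
      best_count = count;
      best_i = i;
      best_j = j;
    }
  }
  return List::create(_["i"] = best_i + 1, _["j"] = best_j + 1,
                      _["count"] = best_count);
}
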