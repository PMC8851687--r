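// Low-level image morphology used by the segmentation module:
// connected-component labelling, chamfer distance transform,
// local-maxima seed detection, and seeded geodesic region growing
// with a deterministic lowest-label tie-break.
#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// union-find with path compression
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// Two-pass connected-component labelling of a binary mask.
// connectivity is 4 or 8; labels are 1..k in raster-scan order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  int next = 1;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int up = (r > 0) ? lab(r - 1, c) : 0;
      int left = (c > 0) ? lab(r, c - 1) : 0;
      int ul = (connectivity == 8 && r > 0 && c > 0) ? lab(r - 1, c - 1) : 0;
      int dl = (connectivity == 8 && r < nr - 1 && c > 0) ? lab(r + 1, c - 1) : 0;
      int neigh[4] = {up, left, ul, dl};
      int best = 0;
      for (int k = 0; k < 4; ++k)
        if (neigh[k] > 0 && (best == 0 || neigh[k] < best)) best = neigh[k];
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < 4; ++k)
          if (neigh[k] > 0 && neigh[k] != best) uf_union(parent, neigh[k], best);
      }
    }
  }
  // relabel to consecutive ids
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) {
        int root = uf_find(parent, lab(r, c));
        if (remap[root] == 0) remap[root] = ++out;
        lab(r, c) = remap[root];
      }
  lab.attr("n_labels") = out;
  return lab;
}

// Chamfer (3-4)/3 distance transform: distance from each TRUE pixel to the
// nearest FALSE pixel. Accurate to ~6% of Euclidean, sufficient for seeding.
// [[Rcpp::export(name = ".chamfer_dist")]]
NumericMatrix chamfer_dist(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18, W1 = 1.0, W2 = 4.0 / 3.0;
  NumericMatrix d(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      d(r, c) = mask(r, c) ? INF : 0.0;
  // forward pass
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (d(r, c) == 0.0) continue;
      double v = d(r, c);
      if (r > 0) v = std::min(v, d(r - 1, c) + W1);
      if (c > 0) v = std::min(v, d(r, c - 1) + W1);
      if (r > 0 && c > 0) v = std::min(v, d(r - 1, c - 1) + W2);
      if (r < nr - 1 && c > 0) v = std::min(v, d(r + 1, c - 1) + W2);
      d(r, c) = v;
    }
  // backward pass
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      if (d(r, c) == 0.0) continue;
      double v = d(r, c);
      if (r < nr - 1) v = std::min(v, d(r + 1, c) + W1);
      if (c < nc - 1) v = std::min(v, d(r, c + 1) + W1);
      if (r < nr - 1 && c < nc - 1) v = std::min(v, d(r + 1, c + 1) + W2);
      if (r > 0 && c < nc - 1) v = std::min(v, d(r - 1, c + 1) + W2);
      d(r, c) = v;
    }
  // edge of image counts as background boundary for border objects
  return d;
}

// Seed candidates: pixels that attain the maximum of `values` within a
// (2h+1)^2 window, greedily thinned so accepted seeds are >= min_sep apart
// (higher values win; ties resolved by raster order => deterministic).
// Returns a 2-column 0-based (row, col) matrix.
// [[Rcpp::export(name = ".local_maxima")]]
IntegerMatrix local_maxima(NumericMatrix values, double min_sep, double min_val) {
  int nr = values.nrow(), nc = values.ncol();
  int h = std::max(1, (int)std::ceil(min_sep));
  std::vector<std::tuple<double, int, int>> cand; // (-value, col, row) for sort
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = values(r, c);
      if (v < min_val) continue;
      bool is_max = true;
      for (int dc = -h; dc <= h && is_max; ++dc)
        for (int dr = -h; dr <= h; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (values(rr, cc) > v) { is_max = false; break; }
        }
      if (is_max) cand.push_back(std::make_tuple(-v, c, r));
    }
  std::stable_sort(cand.begin(), cand.end());
  std::vector<int> keep_r, keep_c;
  double sep2 = min_sep * min_sep;
  for (size_t i = 0; i < cand.size(); ++i) {
    int r = std::get<2>(cand[i]), c = std::get<1>(cand[i]);
    bool ok = true;
    for (size_t j = 0; j < keep_r.size(); ++j) {
      double dr = r - keep_r[j], dc = c - keep_c[j];
      if (dr * dr + dc * dc < sep2) { ok = false; break; }
    }
    if (ok) { keep_r.push_back(r); keep_c.push_back(c); }
  }
  IntegerMatrix out(keep_r.size(), 2);
  for (size_t i = 0; i < keep_r.size(); ++i) {
    out(i, 0) = keep_r[i];
    out(i, 1) = keep_c[i];
  }
  return out;
}

// Multi-source geodesic growing (Dijkstra on the 8-connected pixel grid,
// step costs 1 / sqrt(2)). Non-zero entries of `seeds` are the sources and
// carry their label. Growth is restricted to `allowed` pixels and to
// geodesic distance <= max_dist. Equidistant pixels go to the lowest label.
// [[Rcpp::export(name = ".grow_seeds")]]
IntegerMatrix grow_seeds(IntegerMatrix seeds, LogicalMatrix allowed,
                         double max_dist) {
  int nr = seeds.nrow(), nc = seeds.ncol();
  IntegerMatrix lab(nr, nc);
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), 1e18);
  typedef std::tuple<double, int, int> Node; // (dist, label, flat index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && allowed(r, c)) {
        int idx = c * nr + r;
        dist[idx] = 0.0;
        pq.push(std::make_tuple(0.0, seeds(r, c), idx));
      }
  const double SQ2 = std::sqrt(2.0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    double d = std::get<0>(nd);
    int l = std::get<1>(nd), idx = std::get<2>(nd);
    int r = idx % nr, c = idx / nr;
    if (lab[idx] != 0) continue;       // already settled (lowest label won)
    if (d > dist[idx] + 1e-9) continue;
    lab[idx] = l;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!allowed(rr, cc)) continue;
      int jdx = cc * nr + rr;
      if (lab[jdx] != 0) continue;
      double nd2 = d + (k < 4 ? 1.0 : SQ2);
      if (nd2 > max_dist) continue;
      // push also on equal distance so a lower label can still claim the
      // pixel: priority queue orders by (dist, label)
      if (nd2 <= dist[jdx] + 1e-9) {
        dist[jdx] = std::min(dist[jdx], nd2);
        pq.push(std::make_tuple(nd2, l, jdx));
      }
    }
  }
  return lab;
}
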