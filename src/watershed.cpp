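// Deterministic priority-flood watershed.
//
// Seeds are the regional minima of the relief (plateau-aware: a connected
// component of equal value none of whose members has a strictly lower
// neighbour).  Flooding grows the labels one pixel at a time: among all
// unlabeled pixels adjacent to the labeled region, the pixel with the
// smallest (value, row, col) is labeled next, taking the label of its
// labeled neighbour with the smallest (value, row, col).  This tie rule is
// the package's documented queue discipline and makes output bit-stable.
// Pixels outside the mask keep label 0.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

struct QNode {
  double v;
  int r, c;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.v != b.v) return a.v > b.v;
    if (a.r != b.r) return a.r > b.r;
    return a.c > b.c;
  }
};

// [[Rcpp::export]]
IntegerMatrix watershed_pf(const NumericMatrix& relief, int connectivity,
                           const LogicalMatrix& mask) {
  const int H = relief.nrow(), W = relief.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);

  const int n8r[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int n8c[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;

  // ---- seed regional minima (plateau-aware), scan column-major ----
  std::vector<uint8_t> seen((size_t)H * W, 0);
  int next_label = 0;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || seen[(size_t)r0 + (size_t)H * c0]) continue;
      const double v = relief(r0, c0);
      // BFS over the equal-value plateau
      std::vector<std::pair<int, int>> plateau;
      std::queue<std::pair<int, int>> q;
      q.push({r0, c0});
      seen[(size_t)r0 + (size_t)H * c0] = 1;
      bool is_min = true;
      while (!q.empty()) {
        auto pr = q.front(); q.pop();
        plateau.push_back(pr);
        for (int k = 0; k < nn; ++k) {
          const int r = pr.first + n8r[k], c = pr.second + n8c[k];
          if (r < 0 || r >= H || c < 0 || c >= W || !mask(r, c)) continue;
          const double w = relief(r, c);
          if (w < v) { is_min = false; continue; }
          if (w == v && !seen[(size_t)r + (size_t)H * c]) {
            seen[(size_t)r + (size_t)H * c] = 1;
            q.push({r, c});
          }
        }
      }
      if (is_min) {
        ++next_label;
        for (auto& pr : plateau) lab(pr.first, pr.second) = next_label;
      } else {
        // plateau members may belong to minima of other plateaus? no:
        // they are equal-value and have a lower neighbour path, so not seeds
      }
    }
  }

  // ---- priority flood ----
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (lab(r, c) == 0) continue;
      for (int k = 0; k < nn; ++k) {
        const int rr = r + n8r[k], cc = c + n8c[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (mask(rr, cc) && lab(rr, cc) == 0)
          pq.push({relief(rr, cc), rr, cc});
      }
    }

  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    if (lab(nd.r, nd.c) != 0) continue;
    // label of the lowest labeled neighbour by (value, row, col)
    int best_lab = 0; double bv = 0; int br = -1, bc = -1;
    for (int k = 0; k < nn; ++k) {
      const int r = nd.r + n8r[k], c = nd.c + n8c[k];
      if (r < 0 || r >= H || c < 0 || c >= W) continue;
      const int l = lab(r, c);
      if (l == 0) continue;
      const double w = relief(r, c);
      if (best_lab == 0 || w < bv || (w == bv && (r < br || (r == br && c < bc)))) {
        best_lab = l; bv = w; br = r; bc = c;
      }
    }
    if (best_lab == 0) continue;  // cannot happen: pushed by a labeled pixel
    lab(nd.r, nd.c) = best_lab;
    for (int k = 0; k < nn; ++k) {
      const int r = nd.r + n8r[k], c = nd.c + n8c[k];
      if (r < 0 || r >= H || c < 0 || c >= W) continue;
      if (mask(r, c) && lab(r, c) == 0)
        pq.push({relief(r, c), r, c});
    }
  }
  return lab;
}
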