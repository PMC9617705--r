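#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-connected neighborhood offsets
static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Grayscale morphological reconstruction by dilation (8-connectivity).
// Hybrid algorithm: one raster scan, one anti-raster scan, then FIFO-queue
// propagation until the fixpoint of the geodesic dilation of `marker`
// under `mask` is reached. Requires marker <= mask everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have identical dimensions");
  NumericMatrix J(clone(marker));

  // raster scan: neighbors already visited (N+)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = J(i, j);
      for (int k = 0; k < 8; ++k) {
        int y = i + DY[k], x = j + DX[k];
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        if (x < j || (x == j && y < i)) {  // visited in column-major order
          if (J(y, x) > m) m = J(y, x);
        }
      }
      J(i, j) = std::min(m, mask(i, j));
    }
  }
  // anti-raster scan with N-, enqueueing boundary pixels
  std::queue<int> fifo;
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      double m = J(i, j);
      bool enqueue = false;
      for (int k = 0; k < 8; ++k) {
        int y = i + DY[k], x = j + DX[k];
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        if (x > j || (x == j && y > i)) {
          if (J(y, x) > m) m = J(y, x);
        }
      }
      J(i, j) = std::min(m, mask(i, j));
      for (int k = 0; k < 8; ++k) {
        int y = i + DY[k], x = j + DX[k];
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        if (x > j || (x == j && y > i)) {
          if (J(y, x) < J(i, j) && J(y, x) < mask(y, x)) enqueue = true;
        }
      }
      if (enqueue) fifo.push(j * nr + i);
    }
  }
  // propagation
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int i = p % nr, j = p / nr;
    for (int k = 0; k < 8; ++k) {
      int y = i + DY[k], x = j + DX[k];
      if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
      if (J(y, x) < J(i, j) && mask(y, x) != J(y, x)) {
        J(y, x) = std::min(J(i, j), mask(y, x));
        fifo.push(x * nr + y);
      }
    }
  }
  return J;
}

struct FloodEntry {
  double v;
  long long seq;
  int idx;
};
struct FloodCmp {
  bool operator()(const FloodEntry& a, const FloodEntry& b) const {
    if (a.v != b.v) return a.v > b.v;   // min-heap on value
    return a.seq > b.seq;               // FIFO on ties
  }
};

// Marker-based watershed (8-connectivity): seeds are the regional minima of
// the input surface; flooding by a value-ordered priority queue with FIFO
// tie-breaking, so plateau/ridge pixels join the basin that reaches them
// first (regional minima are enumerated in raster order, which resolves
// simultaneous arrivals toward the lower label). Every pixel receives a
// label in 1..n_regions: no unlabeled watershed lines remain.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix g) {
  int nr = g.nrow(), nc = g.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::vector<char> visited(n, 0);
  std::vector<int> stack;
  int nlab = 0;

  // label regional minima: connected plateaus with no strictly lower neighbor
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int p0 = j * nr + i;
      if (visited[p0]) continue;
      double v = g(i, j);
      // BFS over the plateau of equal value
      std::vector<int> plateau;
      bool isMin = true;
      stack.clear();
      stack.push_back(p0);
      visited[p0] = 1;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        plateau.push_back(p);
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < 8; ++k) {
          int y = pi + DY[k], x = pj + DX[k];
          if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
          double w = g(y, x);
          if (w < v) { isMin = false; continue; }
          if (w == v) {
            int q = x * nr + y;
            if (!visited[q]) { visited[q] = 1; stack.push_back(q); }
          }
        }
      }
      if (isMin) {
        ++nlab;
        for (size_t t = 0; t < plateau.size(); ++t)
          lab[plateau[t]] = nlab;
      } else {
        // plateau pixels may belong to another plateau scan? no: equal-value
        // components are disjoint; mark visited but unlabeled (flooded later)
      }
    }
  }

  // priority flood from the minima
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> pq;
  long long seq = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) pq.push({g(i, j), seq++, j * nr + i});

  std::vector<char> queued(n, 0);
  for (int p = 0; p < n; ++p) queued[p] = lab[p] > 0 ? 1 : 0;

  while (!pq.empty()) {
    FloodEntry e = pq.top(); pq.pop();
    int i = e.idx % nr, j = e.idx / nr;
    int L = lab(i, j);
    for (int k = 0; k < 8; ++k) {
      int y = i + DY[k], x = j + DX[k];
      if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
      int q = x * nr + y;
      if (!queued[q]) {
        lab(y, x) = L;
        queued[q] = 1;
        pq.push({g(y, x), seq++, q});
      }
    }
  }
  return lab;
}
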