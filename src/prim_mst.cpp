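#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Squared Euclidean distance between columns a and b of a D x n matrix.
static inline double sqdist(const double* x, int d, int a, int b) {
  const double* xa = x + static_cast<size_t>(a) * d;
  const double* xb = x + static_cast<size_t>(b) * d;
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    const double diff = xa[k] - xb[k];
    s += diff * diff;
  }
  return s;
}

// Core distance of every point: distance to its k-th nearest neighbour
// (the point itself excluded). k = 1 gives the nearest-neighbour distance.
// `xt` is the transposed feature matrix (D x n): points are contiguous
// columns. O(n^2 D) time, O(n k) memory.
// [[Rcpp::export]]
NumericVector core_distances(NumericMatrix xt, int k) {
  const int d = xt.nrow(), n = xt.ncol();
  const double* x = REAL(xt);
  NumericVector out(n);
  if (n < 2) return out;
  if (k > n - 1) k = n - 1;
  std::vector<double> heap;
  heap.reserve(k);
  for (int i = 0; i < n; ++i) {
    heap.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double s = sqdist(x, d, i, j);
      if (static_cast<int>(heap.size()) < k) {
        heap.push_back(s);
        std::push_heap(heap.begin(), heap.end());
      } else if (s < heap.front()) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = s;
        std::push_heap(heap.begin(), heap.end());
      }
    }
    out[i] = std::sqrt(heap.front());
  }
  return out;
}

// Minimum spanning tree of the mutual-reachability graph by Prim's
// algorithm: edge weight = max(d(a, b), core[a], core[b]). With all core
// distances zero this is the plain Euclidean MST. O(n^2 D) time, O(n)
// memory -- no pairwise distance matrix is ever materialised.
// [[Rcpp::export]]
List prim_mst(NumericMatrix xt, NumericVector core) {
  const int d = xt.nrow(), n = xt.ncol();
  if (n < 2)
    return List::create(_["from"] = IntegerVector(0),
                        _["to"] = IntegerVector(0),
                        _["weight"] = NumericVector(0));
  const double* x = REAL(xt);
  std::vector<double> best(n, R_PosInf);
  std::vector<int> from(n, 0);
  std::vector<char> used(n, 0);

  IntegerVector ef(n - 1), et(n - 1);
  NumericVector ew(n - 1);

  int cur = 0;
  used[0] = 1;
  for (int it = 0; it < n - 1; ++it) {
    double mind = R_PosInf;
    int arg = -1;
    const double ccur = core[cur];
    for (int j = 0; j < n; ++j) {
      if (used[j]) continue;
      double w = std::sqrt(sqdist(x, d, cur, j));
      if (ccur > w) w = ccur;
      if (core[j] > w) w = core[j];
      if (w < best[j]) { best[j] = w; from[j] = cur; }
      if (best[j] < mind) { mind = best[j]; arg = j; }
    }
    ef[it] = from[arg] + 1;
    et[it] = arg + 1;
    ew[it] = best[arg];
    used[arg] = 1;
    cur = arg;
  }
  return List::create(_["from"] = ef, _["to"] = et, _["weight"] = ew);
}
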