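#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Fixed-radius neighbor counting with a uniform grid of cell size = radius.
// For each reference point, candidate neighbors live in the 3x3 block of grid
// cells around it; exact Euclidean distance (<= radius, inclusive) decides.
// When id vectors are supplied, a neighbor sharing its id with the reference
// is skipped so a point never counts itself.

static inline int64_t cellKey(int ix, int iy) {
  return (static_cast<int64_t>(ix) << 32) ^ static_cast<uint32_t>(iy);
}

// [[Rcpp::export]]
IntegerVector cpp_count_neighbors(NumericVector rx, NumericVector ry,
                                  NumericVector nx, NumericVector ny,
                                  double radius,
                                  IntegerVector rid, IntegerVector nid) {
  const int nr = rx.size();
  const int nn = nx.size();
  const bool useIds = (rid.size() == nr) && (nid.size() == nn);
  IntegerVector out(nr);
  if (nn == 0 || nr == 0) return out;

  const double r2 = radius * radius;
  double x0 = nx[0], y0 = ny[0];
  for (int j = 1; j < nn; ++j) {
    if (nx[j] < x0) x0 = nx[j];
    if (ny[j] < y0) y0 = ny[j];
  }
  const double inv = 1.0 / radius;

  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(nn * 2);
  for (int j = 0; j < nn; ++j) {
    int ix = static_cast<int>(std::floor((nx[j] - x0) * inv));
    int iy = static_cast<int>(std::floor((ny[j] - y0) * inv));
    grid[cellKey(ix, iy)].push_back(j);
  }

  for (int i = 0; i < nr; ++i) {
    const double xi = rx[i], yi = ry[i];
    const int cx = static_cast<int>(std::floor((xi - x0) * inv));
    const int cy = static_cast<int>(std::floor((yi - y0) * inv));
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
          grid.find(cellKey(cx + dx, cy + dy));
        if (it == grid.end()) continue;
        const std::vector<int>& bucket = it->second;
        for (size_t b = 0; b < bucket.size(); ++b) {
          const int j = bucket[b];
          if (useIds && rid[i] == nid[j]) continue;
          const double ddx = nx[j] - xi;
          const double ddy = ny[j] - yi;
          if (ddx * ddx + ddy * ddy <= r2) ++cnt;
        }
      }
    }
    out[i] = cnt;
  }
  return out;
}
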