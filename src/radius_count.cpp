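#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Exact neighbour counting on a uniform grid of cell size = radius: only
// the 27 cells around a point can contain neighbours, and every candidate
// pair is distance-checked. The query point itself is never counted.
// [[Rcpp::export(name = ".radius_counts_cpp")]]
IntegerVector radius_counts_cpp(NumericMatrix xyz, double radius) {
  const int n = xyz.nrow();
  IntegerVector counts(n);
  if (n == 0) return counts;
  const double r2 = radius * radius;
  std::unordered_map<uint64_t, std::vector<int> > grid;
  grid.reserve(static_cast<size_t>(n));
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = xyz(i, 0); py[i] = xyz(i, 1); pz[i] = xyz(i, 2);
  }
  std::vector<int64_t> cx(n), cy(n), cz(n);
  auto key = [](int64_t a, int64_t b, int64_t c) -> uint64_t {
    // pack 21-bit signed cell coordinates into one 64-bit key
    const uint64_t m = (1ULL << 21) - 1;
    return ((static_cast<uint64_t>(a) & m) << 42) |
           ((static_cast<uint64_t>(b) & m) << 21) |
           (static_cast<uint64_t>(c) & m);
  };
  for (int i = 0; i < n; ++i) {
    cx[i] = static_cast<int64_t>(std::floor(px[i] / radius));
    cy[i] = static_cast<int64_t>(std::floor(py[i] / radius));
    cz[i] = static_cast<int64_t>(std::floor(pz[i] / radius));
    grid[key(cx[i], cy[i], cz[i])].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    const double xi = px[i], yi = py[i], zi = pz[i];
    int cnt = 0;
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          auto it = grid.find(key(cx[i] + ox, cy[i] + oy, cz[i] + oz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            const double dx = px[j] - xi;
            const double dy = py[j] - yi;
            const double dz = pz[j] - zi;
            if (dx * dx + dy * dy + dz * dz <= r2) ++cnt;
          }
        }
    counts[i] = cnt;
  }
  return counts;
}
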