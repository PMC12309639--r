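#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Priority-flood depression filling (Barnes et al. style) with an epsilon
// gradient so every filled flat drains: each cell is raised to at least
// (spill elevation + eps per step), guaranteeing a strictly descending
// 8-connected path from every land cell to a seed (sea-adjacent or grid-edge
// land cell).

struct PfCell {
  double z;
  long long ord;
  int r, c;
};
struct PfCmp {
  bool operator()(const PfCell &a, const PfCell &b) const {
    if (a.z != b.z) return a.z > b.z;
    return a.ord > b.ord;  // FIFO among equal elevations -> deterministic
  }
};

// [[Rcpp::export]]
NumericMatrix fill_depressions_cpp(NumericMatrix dem, LogicalMatrix land,
                                   double eps) {
  const int nr = dem.nrow(), nc = dem.ncol();
  static const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  static const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  NumericMatrix out(nr, nc);
  std::vector<char> done(static_cast<size_t>(nr) * nc, 0);
  std::priority_queue<PfCell, std::vector<PfCell>, PfCmp> pq;
  long long ord = 0;

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!land(r, c)) { out(r, c) = NA_REAL; continue; }
      out(r, c) = dem(r, c);
      bool seed = false;
      for (int k = 0; k < 8 && !seed; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !land(rr, cc))
          seed = true;  // drains off-grid or into the sea
      }
      if (seed) pq.push({dem(r, c), ord++, r, c});
    }
  if (pq.empty()) stop("no land cell with an outlet (all-sea grid?)");

  while (!pq.empty()) {
    PfCell cur = pq.top();
    pq.pop();
    size_t idx = static_cast<size_t>(cur.r) * nc + cur.c;
    if (done[idx]) continue;
    done[idx] = 1;
    out(cur.r, cur.c) = cur.z;
    for (int k = 0; k < 8; ++k) {
      int rr = cur.r + dr[k], cc = cur.c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!land(rr, cc)) continue;
      size_t nidx = static_cast<size_t>(rr) * nc + cc;
      if (done[nidx]) continue;
      double nz = dem(rr, cc);
      if (nz < cur.z + eps) nz = cur.z + eps;
      pq.push({nz, ord++, rr, cc});
    }
  }
  return out;
}
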