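#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Uniform-grid neighbor list: pairs of particles from different clusters
// within `h` of each other (2D binning; the particle plane is xy).
// `idx` are 1-based particle indices; `cluster` their fiber ids.
// [[Rcpp::export(rng = false)]]
IntegerMatrix grid_neighbor_pairs(NumericMatrix pos, IntegerVector idx,
                                  IntegerVector cluster, double h) {
  const int n = idx.size();
  std::unordered_map<long long, std::vector<int> > cells;
  std::vector<long long> key(n);
  const double inv = 1.0 / h;
  for (int k = 0; k < n; ++k) {
    const int p = idx[k] - 1;
    const long long cx = (long long)std::floor(pos(p, 0) * inv);
    const long long cy = (long long)std::floor(pos(p, 1) * inv);
    key[k] = (cx << 32) ^ (cy & 0xffffffffLL);
    cells[key[k]].push_back(k);
  }
  const double h2 = h * h;
  std::vector<int> vi, vj;
  const int offx[5] = {0, 1, 1, 0, -1};
  const int offy[5] = {0, 0, 1, 1, 1};
  for (int k = 0; k < n; ++k) {
    const int p = idx[k] - 1;
    const long long cx = (long long)std::floor(pos(p, 0) * inv);
    const long long cy = (long long)std::floor(pos(p, 1) * inv);
    for (int o = 0; o < 5; ++o) {
      const long long nk = ((cx + offx[o]) << 32) ^ ((cy + offy[o]) & 0xffffffffLL);
      auto it = cells.find(nk);
      if (it == cells.end()) continue;
      for (int m : it->second) {
        // same cell: count each pair once; neighbor cell: stencil is half
        if (o == 0 && m <= k) continue;
        if (cluster[k] == cluster[m]) continue;
        const int q = idx[m] - 1;
        const double dx = pos(q, 0) - pos(p, 0);
        const double dy = pos(q, 1) - pos(p, 1);
        const double dz = pos(q, 2) - pos(p, 2);
        if (dx * dx + dy * dy + dz * dz <= h2) {
          vi.push_back(idx[k]);
          vj.push_back(idx[m]);
        }
      }
    }
  }
  IntegerMatrix out(vi.size(), 2);
  for (size_t k = 0; k < vi.size(); ++k) {
    out(k, 0) = vi[k];
    out(k, 1) = vj[k];
  }
  colnames(out) = CharacterVector::create("i", "j");
  return out;
}
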