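#include <Rcpp.h>
using namespace Rcpp;

// Candidate (vertex, surface) pairs for vertex-insert detection: vertex
// inside the tolerance-expanded bounding box of a surface it is not "near"
// (near = shares a surface with any surface of s). Surfaces are described
// by the flattened cycle arrays (va, grp); boxes are computed here.
// [[Rcpp::export(rng = false)]]
IntegerMatrix penetration_candidates(NumericMatrix pos, IntegerVector vids,
                                     IntegerVector va, IntegerVector grp,
                                     int nS, LogicalMatrix near, double tol) {
  const R_xlen_t nt = va.size();
  std::vector<double> x0(nS, R_PosInf), x1(nS, R_NegInf),
                      y0(nS, R_PosInf), y1(nS, R_NegInf);
  for (R_xlen_t t = 0; t < nt; ++t) {
    const int s = grp[t] - 1, a = va[t] - 1;
    const double x = pos(a, 0), y = pos(a, 1);
    if (x < x0[s]) x0[s] = x;
    if (x > x1[s]) x1[s] = x;
    if (y < y0[s]) y0[s] = y;
    if (y > y1[s]) y1[s] = y;
  }
  std::vector<int> hv, hs;
  const int nv = vids.size();
  for (int s = 0; s < nS; ++s) {
    const double bx0 = x0[s] - tol, bx1 = x1[s] + tol;
    const double by0 = y0[s] - tol, by1 = y1[s] + tol;
    for (int k = 0; k < nv; ++k) {
      const int v = vids[k] - 1;
      const double x = pos(v, 0), y = pos(v, 1);
      if (x >= bx0 && x <= bx1 && y >= by0 && y <= by1 && !near(v, s)) {
        hv.push_back(k + 1);
        hs.push_back(s + 1);
      }
    }
  }
  IntegerMatrix out(hv.size(), 2);
  for (size_t k = 0; k < hv.size(); ++k) {
    out(k, 0) = hv[k];
    out(k, 1) = hs[k];
  }
  return out;
}
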