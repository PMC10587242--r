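#include <Rcpp.h>
using namespace Rcpp;

// Fan-triangulation measures for all surfaces at once. One triangle per
// cycle slot: (vertex va, next vertex vb, surface centroid). Areas are sums
// of triangle areas; perimeters sums of straight-edge lengths.
// [[Rcpp::export(rng = false)]]
List fan_measures(NumericMatrix pos, IntegerVector va, IntegerVector vb,
                  IntegerVector grp, int nS) {
  const R_xlen_t nt = va.size();
  NumericMatrix cent(nS, 3);
  IntegerVector cnt(nS);
  for (R_xlen_t t = 0; t < nt; ++t) {
    const int s = grp[t] - 1, a = va[t] - 1;
    cent(s, 0) += pos(a, 0); cent(s, 1) += pos(a, 1); cent(s, 2) += pos(a, 2);
    cnt[s] += 1;
  }
  for (int s = 0; s < nS; ++s) {
    if (cnt[s] > 0) {
      cent(s, 0) /= cnt[s]; cent(s, 1) /= cnt[s]; cent(s, 2) /= cnt[s];
    }
  }
  NumericVector area(nS), perim(nS);
  for (R_xlen_t t = 0; t < nt; ++t) {
    const int s = grp[t] - 1, a = va[t] - 1, b = vb[t] - 1;
    const double ux = pos(a, 0) - cent(s, 0), uy = pos(a, 1) - cent(s, 1),
                 uz = pos(a, 2) - cent(s, 2);
    const double vx = pos(b, 0) - cent(s, 0), vy = pos(b, 1) - cent(s, 1),
                 vz = pos(b, 2) - cent(s, 2);
    const double ex = uy * vz - uz * vy;
    const double ey = uz * vx - ux * vz;
    const double ez = ux * vy - uy * vx;
    area[s] += 0.5 * std::sqrt(ex * ex + ey * ey + ez * ez);
    const double dx = pos(b, 0) - pos(a, 0), dy = pos(b, 1) - pos(a, 1),
                 dz = pos(b, 2) - pos(a, 2);
    perim[s] += std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return List::create(_["area"] = area, _["perim"] = perim,
                      _["centroid"] = cent);
}

// Fused per-surface force pass: adds, for each surface S,
//   gA[S] * d(area)/dr + gL[S] * d(perimeter)/dr + gE2[S] * d(sum e^2)/dr
// to the vertex force matrix. The area gradient follows the fan
// triangulation with the centroid as a dependent point (each cycle vertex
// enters the centroid with weight 1/n).
// [[Rcpp::export(rng = false)]]
NumericMatrix surface_constraint_forces(NumericMatrix pos, IntegerVector va,
                                        IntegerVector vb, IntegerVector grp,
                                        IntegerVector slen, NumericVector gA,
                                        NumericVector gL, NumericVector gE2,
                                        int nout) {
  const R_xlen_t nt = va.size();
  const int nS = slen.size();
  NumericMatrix F(nout, 3);
  NumericMatrix cent(nS, 3);
  IntegerVector cnt(nS);
  for (R_xlen_t t = 0; t < nt; ++t) {
    const int s = grp[t] - 1, a = va[t] - 1;
    cent(s, 0) += pos(a, 0); cent(s, 1) += pos(a, 1); cent(s, 2) += pos(a, 2);
    cnt[s] += 1;
  }
  for (int s = 0; s < nS; ++s) {
    if (cnt[s] > 0) {
      cent(s, 0) /= cnt[s]; cent(s, 1) /= cnt[s]; cent(s, 2) /= cnt[s];
    }
  }
  NumericMatrix Rs(nS, 3);  // per-surface sum of (P + Q) for the centroid term
  for (R_xlen_t t = 0; t < nt; ++t) {
    const int s = grp[t] - 1, a = va[t] - 1, b = vb[t] - 1;
    const double cA = gA[s], cL = gL[s], cE = gE2[s];
    if (cA != 0.0) {
      const double ux = pos(a, 0) - cent(s, 0), uy = pos(a, 1) - cent(s, 1),
                   uz = pos(a, 2) - cent(s, 2);
      const double vx = pos(b, 0) - cent(s, 0), vy = pos(b, 1) - cent(s, 1),
                   vz = pos(b, 2) - cent(s, 2);
      double ex = uy * vz - uz * vy;
      double ey = uz * vx - ux * vz;
      double ez = ux * vy - uy * vx;
      const double nn = std::sqrt(ex * ex + ey * ey + ez * ez);
      if (nn > 1e-12) {
        ex /= nn; ey /= nn; ez /= nn;   // unit triangle normal
        // P = v x nhat (d|eta|/da), Q = nhat x u (d|eta|/db)
        const double Px = vy * ez - vz * ey;
        const double Py = vz * ex - vx * ez;
        const double Pz = vx * ey - vy * ex;
        const double Qx = ey * uz - ez * uy;
        const double Qy = ez * ux - ex * uz;
        const double Qz = ex * uy - ey * ux;
        F(a, 0) += 0.5 * cA * Px; F(a, 1) += 0.5 * cA * Py;
        F(a, 2) += 0.5 * cA * Pz;
        F(b, 0) += 0.5 * cA * Qx; F(b, 1) += 0.5 * cA * Qy;
        F(b, 2) += 0.5 * cA * Qz;
        Rs(s, 0) += Px + Qx; Rs(s, 1) += Py + Qy; Rs(s, 2) += Pz + Qz;
      }
    }
    if (cL != 0.0 || cE != 0.0) {
      const double dx = pos(b, 0) - pos(a, 0), dy = pos(b, 1) - pos(a, 1),
                   dz = pos(b, 2) - pos(a, 2);
      if (cL != 0.0) {
        const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r > 1e-12) {
          const double w = cL / r;
          F(a, 0) -= w * dx; F(a, 1) -= w * dy; F(a, 2) -= w * dz;
          F(b, 0) += w * dx; F(b, 1) += w * dy; F(b, 2) += w * dz;
        }
      }
      if (cE != 0.0) {
        F(a, 0) -= 2 * cE * dx; F(a, 1) -= 2 * cE * dy; F(a, 2) -= 2 * cE * dz;
        F(b, 0) += 2 * cE * dx; F(b, 1) += 2 * cE * dy; F(b, 2) += 2 * cE * dz;
      }
    }
  }
  // centroid-dependence correction of the area gradient
  for (R_xlen_t t = 0; t < nt; ++t) {
    const int s = grp[t] - 1, a = va[t] - 1;
    const double cA = gA[s];
    if (cA != 0.0) {
      const double w = 0.5 * cA / slen[s];
      F(a, 0) -= w * Rs(s, 0); F(a, 1) -= w * Rs(s, 1); F(a, 2) -= w * Rs(s, 2);
    }
  }
  return F;
}
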