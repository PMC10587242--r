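#include <Rcpp.h>
using namespace Rcpp;

// Morse-form pairwise forces accumulated onto particle rows.
// U(r) = k (1 - exp(-a (r - r0)))^2, truncated at the cutoff.
// Returns an nout x 3 matrix with the force on each particle; the force on
// j is -dU/dr * rhat(i->j), equal and opposite on i.
// [[Rcpp::export(rng = false)]]
NumericMatrix morse_pair_forces(NumericMatrix pos, IntegerVector i,
                                IntegerVector j, double k, double a,
                                double r0, double cutoff, int nout) {
  const R_xlen_t np = i.size();
  NumericMatrix F(nout, 3);
  const double cut2 = cutoff * cutoff;
  for (R_xlen_t p = 0; p < np; ++p) {
    const int ii = i[p] - 1, jj = j[p] - 1;
    const double dx = pos(jj, 0) - pos(ii, 0);
    const double dy = pos(jj, 1) - pos(ii, 1);
    const double dz = pos(jj, 2) - pos(ii, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > cut2 || r2 < 1e-24) continue;
    const double r = std::sqrt(r2);
    const double ex = std::exp(-a * (r - r0));
    const double g = -2.0 * k * a * ex * (1.0 - ex) / r;  // -dU/dr / r
    const double fx = g * dx, fy = g * dy, fz = g * dz;
    F(jj, 0) += fx; F(jj, 1) += fy; F(jj, 2) += fz;
    F(ii, 0) -= fx; F(ii, 1) -= fy; F(ii, 2) -= fz;
  }
  return F;
}
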