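#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear interpolation of `m` at fractional (row, col), 0-based.
// Returns NA outside the grid.
static inline double bilin(const NumericMatrix &m, double r, double c) {
  int nr = m.nrow(), nc = m.ncol();
  if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0)
    return NA_REAL;
  int r0 = (int)std::floor(r); if (r0 > nr - 2) r0 = nr - 2; if (r0 < 0) r0 = 0;
  int c0 = (int)std::floor(c); if (c0 > nc - 2) c0 = nc - 2; if (c0 < 0) c0 = 0;
  double fr = r - r0, fc = c - c0;
  // accumulate only corners with nonzero weight: an NA corner must not
  // poison an on-grid-line sample (0 * NA is NaN in IEEE arithmetic)
  const double w[4] = {(1 - fr) * (1 - fc), fr * (1 - fc),
                       (1 - fr) * fc, fr * fc};
  const double v[4] = {m(r0, c0), m(r0 + 1, c0),
                       m(r0, c0 + 1), m(r0 + 1, c0 + 1)};
  double out = 0.0;
  for (int k = 0; k < 4; ++k) {
    if (w[k] == 0.0) continue;
    if (!R_finite(v[k])) return NA_REAL;
    out += w[k] * v[k];
  }
  return out;
}

struct Offset { double dr, dc, d2; };

// 2D gamma with local dose normalisation.
//
// eval, ref     : dose matrices on the same grid
// roi           : logical matrix, gamma evaluated where TRUE
// pitch_mm      : pixel pitch in mm
// dose_frac     : dose criterion as a fraction (0.03 for 3%)
// dist_mm       : distance-to-agreement criterion in mm
// search_mm     : search radius in mm
// step_mm       : search-grid step in mm (sub-pixel via bilinear interp)
//
// gamma(r) = min over search positions p of
//   sqrt( |p - r|^2 / dist^2 + (De(r) - Dr(p))^2 / (dose_frac * Dr(p))^2 )
// Offsets are scanned in increasing distance so the search can stop as
// soon as the pure distance term exceeds the current minimum.
// [[Rcpp::export]]
NumericMatrix gamma2d_cpp(NumericMatrix eval, NumericMatrix ref,
                          LogicalMatrix roi, double pitch_mm,
                          double dose_frac, double dist_mm,
                          double search_mm, double step_mm) {
  int nr = eval.nrow(), nc = eval.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);

  int nstep = (int)std::floor(search_mm / step_mm + 1e-9);
  std::vector<Offset> offs;
  offs.reserve((2 * nstep + 1) * (2 * nstep + 1));
  for (int i = -nstep; i <= nstep; ++i)
    for (int j = -nstep; j <= nstep; ++j) {
      double dr = i * step_mm, dc = j * step_mm;
      double d2 = dr * dr + dc * dc;
      if (d2 <= search_mm * search_mm + 1e-9)
        offs.push_back({dr, dc, d2});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.d2 < b.d2; });

  double inv_d2 = 1.0 / (dist_mm * dist_mm);

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!roi(r, c)) continue;
      double de = eval(r, c);
      if (!R_finite(de)) continue;
      double gmin2 = R_PosInf;
      for (const Offset &o : offs) {
        double dist_term = o.d2 * inv_d2;
        if (dist_term >= gmin2) break;  // offsets sorted by distance
        double rr = r + o.dr / pitch_mm;
        double cc = c + o.dc / pitch_mm;
        double dref = bilin(ref, rr, cc);
        if (!R_finite(dref) || dref <= 0.0) continue;
        double denom = dose_frac * dref;
        double dd = (de - dref) / denom;
        double g2 = dist_term + dd * dd;
        if (g2 < gmin2) gmin2 = g2;
      }
      if (R_finite(gmin2)) out(r, c) = std::sqrt(gmin2);
    }
  }
  return out;
}
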