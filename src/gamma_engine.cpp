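#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Global 2D gamma evaluated at measured pixels against a pre-interpolated
// fine-pitch planned distribution.
//
// measured: ny x nx dose matrix (Gy), pixel pitch = k * pitch
// fine:     ((ny-1)*k+1) x ((nx-1)*k+1) planned dose at `pitch` mm,
//           aligned so measured pixel (i, j) sits at fine node (i*k, j*k)
// dta:      distance criterion (mm), doseTol: dose criterion (Gy)
// thresholdGy: measured pixels below this are not evaluated (NA)
// radiusMm: search radius; pixels whose search disc exits the fine grid
//           are marked NA (invalid, not failed)
//
// Offsets are visited in order of increasing distance with an early exit
// once the distance term alone exceeds the running minimum.
// [[Rcpp::export]]
NumericMatrix gamma_engine_cpp(NumericMatrix measured, NumericMatrix fine,
                               int k, double pitch, double dta,
                               double doseTol, double thresholdGy,
                               double radiusMm) {
  const int ny = measured.nrow(), nx = measured.ncol();
  const int nyf = fine.nrow(), nxf = fine.ncol();
  // disc membership decided on the integer lattice so the candidate set
  // is identical across implementations regardless of rounding
  const int rmax = (int)std::floor(radiusMm / pitch + 1e-9);
  const int l2max = rmax * rmax;

  struct Off { int di, dj; double rr; };  // rr = (r/dta)^2
  std::vector<Off> offs;
  offs.reserve((2 * rmax + 1) * (2 * rmax + 1));
  for (int di = -rmax; di <= rmax; ++di)
    for (int dj = -rmax; dj <= rmax; ++dj) {
      int l2 = di * di + dj * dj;
      if (l2 <= l2max)
        offs.push_back({di, dj, (double)l2 * pitch * pitch / (dta * dta)});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Off& a, const Off& b) { return a.rr < b.rr; });

  NumericMatrix out(ny, nx);
  std::fill(out.begin(), out.end(), NA_REAL);

  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      double m = measured(i, j);
      if (NumericVector::is_na(m) || m < thresholdGy) continue;
      int fi = i * k, fj = j * k;
      if (fi - rmax < 0 || fi + rmax > nyf - 1 ||
          fj - rmax < 0 || fj + rmax > nxf - 1)
        continue;  // search disc exits the planned grid: invalid
      double best = R_PosInf;
      for (const Off& o : offs) {
        if (o.rr >= best) break;
        double p = fine(fi + o.di, fj + o.dj);
        if (NumericVector::is_na(p)) continue;
        double dd = (m - p) / doseTol;
        double cand = o.rr + dd * dd;
        if (cand < best) best = cand;
      }
      if (R_finite(best)) out(i, j) = std::sqrt(best);
    }
  }
  return out;
}
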