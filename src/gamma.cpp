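#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Offset { int di, dj, dk; double d2; };

// Gamma map with local (reference-dose) normalisation.
//
// Search strategy: voxel centres within searchRadius are visited in order of
// increasing distance with early termination once the distance term alone
// exceeds the running minimum. With subvoxel = true the search additionally
// minimises gamma^2 analytically along every axis-aligned lattice edge in
// the neighbourhood: the interpolated evaluated dose is linear on an edge,
// so gamma^2 is an exact 1-D quadratic there. This resolves steep dose
// gradients (e.g. a distal SOBP edge crossing several criterion widths per
// voxel) that a fixed sub-voxel sampling lattice cannot.
// twoD restricts the search to the slice plane. Reference voxels below
// cutoffAbs get NA.
// [[Rcpp::export(name = ".cppGammaMap")]]
NumericVector cppGammaMap(NumericVector ref, NumericVector eval,
                          IntegerVector dims, NumericVector spacing,
                          double ddFrac, double dta, double cutoffAbs,
                          double searchRadius, bool subvoxel, bool twoD) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  std::vector<Offset> offs;
  double R2 = searchRadius * searchRadius;
  int mx = (int)std::floor(searchRadius / sx);
  int my = (int)std::floor(searchRadius / sy);
  int mz = twoD ? 0 : (int)std::floor(searchRadius / sz);
  for (int k = -mz; k <= mz; ++k)
    for (int j = -my; j <= my; ++j)
      for (int i = -mx; i <= mx; ++i) {
        double dx = i * sx, dy = j * sy, dz = k * sz;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= R2) offs.push_back({i, j, k, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.d2 < b.d2; });

  const double* rp = ref.begin();
  const double* ep = eval.begin();
  double dta2 = dta * dta;
  // edge directions (voxel steps and their physical lengths)
  const int eDi[3] = {1, 0, 0}, eDj[3] = {0, 1, 0}, eDk[3] = {0, 0, 1};
  const double eLen[3] = {sx, sy, sz};

  NumericVector gamma(ref.size(), NA_REAL);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
        double D = rp[idx];
        if (D < cutoffAbs) continue;
        double tol2 = ddFrac * D * ddFrac * D;
        double best = R_PosInf;
        // pass 1: voxel centres, sorted by distance, early exit
        for (const Offset& o : offs) {
          double distTerm = o.d2 / dta2;
          if (distTerm >= best) break;
          int ii = i + o.di, jj = j + o.dj, kk = k + o.dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
              kk >= nz) continue;
          double dd = ep[ii + (size_t)nx * (jj + (size_t)ny * kk)] - D;
          double g2 = distTerm + dd * dd / tol2;
          if (g2 < best) best = g2;
        }
        // pass 2: analytic minimum on each lattice edge of the
        // neighbourhood (quadratic in the edge parameter)
        if (subvoxel) {
          for (const Offset& o : offs) {
            int ii = i + o.di, jj = j + o.dj, kk = k + o.dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                kk >= nz) continue;
            double d0 = ep[ii + (size_t)nx * (jj + (size_t)ny * kk)] - D;
            double px = o.di * sx, py = o.dj * sy, pz = o.dk * sz;
            int nDir = twoD ? 2 : 3;
            for (int e = 0; e < nDir; ++e) {
              int i1 = ii + eDi[e], j1 = jj + eDj[e], k1 = kk + eDk[e];
              if (i1 >= nx || j1 >= ny || k1 >= nz) continue;
              double d1 = ep[i1 + (size_t)nx * (j1 + (size_t)ny * k1)] - D;
              double qx = eDi[e] * eLen[e], qy = eDj[e] * eLen[e],
                     qz = eDk[e] * eLen[e];
              // f(t) = (d0 + (d1-d0) t)^2/tol2 + |p + t q|^2/dta2
              double dd = d1 - d0;
              double A = dd * dd / tol2 +
                (qx * qx + qy * qy + qz * qz) / dta2;
              double B = 2.0 * (d0 * dd / tol2 +
                                (px * qx + py * qy + pz * qz) / dta2);
              double C = d0 * d0 / tol2 +
                (px * px + py * py + pz * pz) / dta2;
              double t = (A > 0) ? -B / (2.0 * A) : 0.0;
              if (t < 0) t = 0; else if (t > 1) t = 1;
              double g2 = (A * t + B) * t + C;
              if (g2 < best) best = g2;
            }
          }
        }
        gamma[idx] = std::sqrt(best);
      }
  return gamma;
}
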