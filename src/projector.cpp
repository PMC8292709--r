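#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// bilinear sample of img (nx x ny) at fractional 0-based voxel coords;
// contributions outside the grid are 0 (air)
static inline double bilin(const double* img, int nx, int ny,
                           double x, double y) {
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
  double fx = x - i0, fy = y - j0, out = 0.0;
  for (int di = 0; di <= 1; ++di) {
    int i = i0 + di;
    if (i < 0 || i >= nx) continue;
    double wx = di ? fx : 1.0 - fx;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= ny) continue;
      double wy = dj ? fy : 1.0 - fy;
      out += wx * wy * img[i + (size_t)nx * j];
    }
  }
  return out;
}

// Parallel-beam forward projection of one slice (mm-weighted line integrals).
// Rays are sampled at 'step' mm with midpoint quadrature; rotation centre is
// the grid centre. Detector bin t_j = (j - (nBins-1)/2) * binSpacing.
// [[Rcpp::export(name = ".cppForwardProject")]]
NumericMatrix cppForwardProject(NumericMatrix img, NumericVector spacing,
                                NumericVector angles, int nBins,
                                double binSpacing, double step) {
  int nx = img.nrow(), ny = img.ncol(), nAng = angles.size();
  double sx = spacing[0], sy = spacing[1];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double halfDiag = 0.5 * std::sqrt(std::pow(nx * sx, 2) +
                                    std::pow(ny * sy, 2));
  int nSamp = (int)std::ceil(2.0 * halfDiag / step);
  NumericMatrix sino(nBins, nAng);
  const double* p = img.begin();
  for (int a = 0; a < nAng; ++a) {
    double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int b = 0; b < nBins; ++b) {
      double t = (b - (nBins - 1) / 2.0) * binSpacing;
      double acc = 0.0;
      for (int k = 0; k < nSamp; ++k) {
        double s = -halfDiag + (k + 0.5) * step;
        double x = cx + (t * ca - s * sa) / sx;
        double y = cy + (t * sa + s * ca) / sy;
        acc += bilin(p, nx, ny, x, y);
      }
      sino(b, a) = acc * step;
    }
  }
  return sino;
}

// Pixel-driven back projection of a filtered sinogram; linear interpolation
// along the detector axis; scaled by pi / nAngles.
// [[Rcpp::export(name = ".cppBackProject")]]
NumericMatrix cppBackProject(NumericMatrix fsino, NumericVector angles,
                             double binSpacing, int nx, int ny,
                             NumericVector spacing) {
  int nBins = fsino.nrow(), nAng = angles.size();
  double sx = spacing[0], sy = spacing[1];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double tc = (nBins - 1) / 2.0;
  NumericMatrix out(nx, ny);
  for (int a = 0; a < nAng; ++a) {
    double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    const double* col = &fsino(0, a);
    for (int j = 0; j < ny; ++j) {
      double y = (j - cy) * sy;
      for (int i = 0; i < nx; ++i) {
        double x = (i - cx) * sx;
        double tb = (x * ca + y * sa) / binSpacing + tc;
        int b0 = (int)std::floor(tb);
        if (b0 < 0 || b0 >= nBins - 1) continue;
        double f = tb - b0;
        out(i, j) += (1.0 - f) * col[b0] + f * col[b0 + 1];
      }
    }
  }
  double w = M_PI / nAng;
  for (int k = 0; k < nx * ny; ++k) out[k] *= w;
  return out;
}
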