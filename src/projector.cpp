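#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Image convention shared with the R side:
//   values[i, j] (row i, col j) sits at x = (j - (n+1)/2) * px,
//                                      y = ((n+1)/2 - i) * px
// i.e. row 1 is the top of the image and the grid center is the isocenter.
// Lengths in mm, attenuation in 1/cm; line integrals are dimensionless
// (mu [1/cm] * path [mm] / 10).

// bilinear sample at continuous 0-based index coordinates (ci = row,
// cj = column); the caller guarantees ci, cj in [0, n-2] except for a
// narrow boundary band handled by clamping
static inline double bilinearIdx(const double *img, int n, double ci,
                                 double cj) {
  int i0 = (int)ci, j0 = (int)cj;
  if (i0 > n - 2) i0 = n - 2;
  if (j0 > n - 2) j0 = n - 2;
  const double fi = ci - i0, fj = cj - j0;
  const double *col = img + (size_t)j0 * n + i0;
  const double v00 = col[0], v10 = col[1];
  const double v01 = col[n], v11 = col[n + 1];
  return (1 - fi) * ((1 - fj) * v00 + fj * v01) +
         fi * ((1 - fj) * v10 + fj * v11);
}

// Ray-driven fan-beam projector: for view angle beta the source sits at
// O + a*(cos b, sin b), the flat detector passes through O - b*(cos b, sin b)
// with in-plane coordinate u along (-sin b, cos b); O = (isoOffset, 0) is the
// rotation center.  Each line integral is accumulated by marching the ray
// across the image bounding box with bilinear interpolation.
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(const NumericMatrix &img, double px,
                                  double a, double bdist,
                                  const NumericVector &angles,
                                  const NumericVector &u, double isoOffset,
                                  double step, int oversample) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("image must be square");
  const int nv = angles.size(), nd = u.size();
  NumericMatrix out(nv, nd);
  const double *pimg = &img[0];
  const double half = n * px / 2.0;
  const int os = oversample < 1 ? 1 : oversample;
  // sub-ray offsets spanning one detector bin (bin pitch inferred from u when
  // oversampling; a single bin falls back to the center ray)
  double pitch = 0.0;
  if (nd > 1) pitch = u[1] - u[0];
  for (int iv = 0; iv < nv; ++iv) {
    const double cb = std::cos(angles[iv]), sb = std::sin(angles[iv]);
    const double sx = isoOffset + a * cb, sy = a * sb;
    for (int id = 0; id < nd; ++id) {
      double acc = 0.0;
      for (int k = 0; k < os; ++k) {
        double du = 0.0;
        if (os > 1) du = pitch * ((k + 0.5) / os - 0.5);
        const double uu = u[id] + du;
        const double dx0 = isoOffset - bdist * cb - uu * sb;
        const double dy0 = -bdist * sb + uu * cb;
        double rx = dx0 - sx, ry = dy0 - sy;
        const double len = std::sqrt(rx * rx + ry * ry);
        rx /= len; ry /= len;
        // clip to a box shrunk by half a pixel so the interpolation
        // stencil stays inside the grid (the outermost half-pixel ring is
        // treated as zero, consistent with an image embedded in air)
        const double hb = half - px * 0.5;
        double t0 = 0.0, t1 = len;
        if (std::fabs(rx) > 1e-12) {
          double ta = (-hb - sx) / rx, tb = (hb - sx) / rx;
          if (ta > tb) std::swap(ta, tb);
          t0 = std::max(t0, ta); t1 = std::min(t1, tb);
        } else if (sx < -hb || sx > hb) { continue; }
        if (std::fabs(ry) > 1e-12) {
          double ta = (-hb - sy) / ry, tb = (hb - sy) / ry;
          if (ta > tb) std::swap(ta, tb);
          t0 = std::max(t0, ta); t1 = std::min(t1, tb);
        } else if (sy < -hb || sy > hb) { continue; }
        if (t1 <= t0) continue;
        const int nstep = (int)std::ceil((t1 - t0) / step);
        const double ds = (t1 - t0) / nstep;
        // march in index space: ci (row) decreases with y, cj grows with x
        const double invPx = 1.0 / px, c0 = (n - 1) * 0.5;
        const double tmid = t0 + ds * 0.5;
        double cj = (sx + tmid * rx) * invPx + c0;
        double ci = c0 - (sy + tmid * ry) * invPx;
        const double dcj = ds * rx * invPx, dci = -ds * ry * invPx;
        double s = 0.0;
        for (int is = 0; is < nstep; ++is, ci += dci, cj += dcj)
          s += bilinearIdx(pimg, n, ci < 0 ? 0 : ci, cj < 0 ? 0 : cj);
        acc += s * ds;
      }
      out(iv, id) = acc / os / 10.0;  // mm * 1/cm -> dimensionless
    }
  }
  return out;
}

// Pixel-driven fan-beam backprojection of a filtered sinogram.  uIso holds
// the detector coordinates rescaled to the isocenter plane (u * a / c); the
// caller applies Delta-beta/2 and distance weights are a^2/U^2 with
// U = a - (r - O).e_source.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(const NumericMatrix &q,
                              const NumericVector &angles,
                              const NumericVector &uIso, double a,
                              double isoOffset, int gridSize, double px) {
  const int nv = angles.size(), nd = uIso.size();
  if (q.nrow() != nv || q.ncol() != nd) stop("sinogram shape mismatch");
  NumericMatrix out(gridSize, gridSize);
  const double u0 = uIso[0];
  const double du = nd > 1 ? (uIso[1] - uIso[0]) : 1.0;
  const double invDu = 1.0 / du;
  std::vector<double> cosb(nv), sinb(nv);
  for (int iv = 0; iv < nv; ++iv) {
    cosb[iv] = std::cos(angles[iv]);
    sinb[iv] = std::sin(angles[iv]);
  }
  // transposed copy: one view's detector row is contiguous
  std::vector<double> qt((size_t)nv * nd);
  for (int iv = 0; iv < nv; ++iv)
    for (int id = 0; id < nd; ++id)
      qt[(size_t)iv * nd + id] = q(iv, id);
  const double c0 = (gridSize - 1) * 0.5;
  double *pout = &out[0];
  // block the pixel loop so each view's detector row is streamed over a
  // cache-resident tile of the image
  const int tile = 24;
  for (int j0t = 0; j0t < gridSize; j0t += tile) {
    const int j1t = std::min(j0t + tile, gridSize);
    for (int iv = 0; iv < nv; ++iv) {
      const double cb = cosb[iv], sb = sinb[iv];
      const double *qrow = &qt[(size_t)iv * nd];
      for (int j = j0t; j < j1t; ++j) {
        const double relx = (j - c0) * px;
        double *ocol = pout + (size_t)j * gridSize;  // column-major
        for (int i = 0; i < gridSize; ++i) {
          const double rely = (c0 - i) * px;
          const double U = a - (relx * cb + rely * sb);
          if (U < 1e-6) continue;
          const double fid = (a * (rely * cb - relx * sb) / U - u0) * invDu;
          if (fid < 0.0 || fid > nd - 1) continue;
          int id0 = (int)fid;
          if (id0 == nd - 1) id0 = nd - 2;
          const double f = fid - id0;
          const double val = (1 - f) * qrow[id0] + f * qrow[id0 + 1];
          ocol[i] += val * (a * a) / (U * U);
        }
      }
    }
  }
  return out;
}
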