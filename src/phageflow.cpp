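#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Unit-intensity image of a straight fluorophore-decorated rod under a
// circular Gaussian PSF: line integral of the PSF along the rod, sampled at
// pixel centres by midpoint quadrature.  Coordinates in micrometres, origin
// at the frame centre, x right, y up; row iy of the returned matrix is the
// pixel row at y = (iy - 0.5 - H/2) * pitch.
// [[Rcpp::export(name = ".render_rod_core")]]
NumericMatrix render_rod_core(int width, int height, double pitch,
                              double x0, double y0, double L,
                              double phi_deg, double sigma, int nq) {
  NumericMatrix img(height, width);
  if (L <= 0.0 || nq < 1) return img;
  double *p = img.begin();
  const double phi = phi_deg * M_PI / 180.0;
  const double cx = std::cos(phi), cy = std::sin(phi);
  const double ds = L / nq;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  // the Gaussian is negligible beyond ~7 sigma; restrict each source's
  // stamp to that window (truncation error ~1e-11 of the peak)
  const int halo = (int)std::ceil(7.0 * sigma / pitch) + 1;
  std::vector<double> gx(width), gy(height);
  for (int m = 0; m < nq; ++m) {
    const double s  = (m + 0.5) * ds;
    const double xs = x0 + s * cx, ys = y0 + s * cy;
    const int ix_c = (int)std::floor(xs / pitch + width / 2.0);
    const int iy_c = (int)std::floor(ys / pitch + height / 2.0);
    const int ix0 = std::max(0, ix_c - halo), ix1 = std::min(width - 1, ix_c + halo);
    const int iy0 = std::max(0, iy_c - halo), iy1 = std::min(height - 1, iy_c + halo);
    if (ix0 > ix1 || iy0 > iy1) continue;
    for (int ix = ix0; ix <= ix1; ++ix) {
      const double dx = (ix + 0.5 - width / 2.0) * pitch - xs;
      gx[ix] = std::exp(-dx * dx * inv2s2);
    }
    for (int iy = iy0; iy <= iy1; ++iy) {
      const double dy = (iy + 0.5 - height / 2.0) * pitch - ys;
      gy[iy] = std::exp(-dy * dy * inv2s2);
    }
    for (int ix = ix0; ix <= ix1; ++ix) {
      const double w = gx[ix] * ds;
      double *col = p + (R_xlen_t)ix * height;
      for (int iy = iy0; iy <= iy1; ++iy)
        col[iy] += w * gy[iy];
    }
  }
  return img;
}

// 5x5 median filter with replicated borders (exact order statistics, so
// integer-valued images stay integer-valued).
// [[Rcpp::export(name = ".median_filter5")]]
NumericMatrix median_filter5(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double buf[25];
  for (int ix = 0; ix < W; ++ix) {
    for (int iy = 0; iy < H; ++iy) {
      int n = 0;
      for (int dx = -2; dx <= 2; ++dx) {
        int jx = std::min(std::max(ix + dx, 0), W - 1);
        for (int dy = -2; dy <= 2; ++dy) {
          int jy = std::min(std::max(iy + dy, 0), H - 1);
          buf[n++] = img(jy, jx);
        }
      }
      std::nth_element(buf, buf + 12, buf + 25);
      out(iy, ix) = buf[12];
    }
  }
  return out;
}

// Sum-squared error between an observed frame and B + I0 * G, with the
// intensity I0 that minimises it computed in closed form (ratio of the
// cross- and auto-correlation of the unit render with the background-
// subtracted data), clamped to I0 >= 0.
// [[Rcpp::export(name = ".sse_with_optimal_intensity")]]
List sse_with_optimal_intensity(NumericMatrix obs, NumericMatrix unit,
                                double B) {
  const R_xlen_t n = obs.size();
  double sgg = 0.0, seg = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = unit[i];
    sgg += g * g;
    seg += (obs[i] - B) * g;
  }
  double I0 = (sgg > 0.0) ? seg / sgg : 0.0;
  if (I0 < 0.0) I0 = 0.0;
  double sse = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double r = obs[i] - B - I0 * unit[i];
    sse += r * r;
  }
  return List::create(_["I0"] = I0, _["sse"] = sse);
}
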