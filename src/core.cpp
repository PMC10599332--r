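// Numerical core: parallel-beam projection, filtered-backprojection
// backprojector, and windowed median filtering. Conventions:
//  - arrays are (row = y, col = x); the rotation axis is the vertical
//    volume axis through the in-plane center ((n-1)/2, 0-based);
//  - angles are radians, counter-clockwise viewed from +z;
//  - the Radon sample for detector coordinate s and integration index t is
//    (x, y) = c + s' * (cos a, sin a) + t' * (-sin a, cos a).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double bilinear(const arma::mat& m, double y, double x) {
  const int ny = m.n_rows, nx = m.n_cols;
  if (y < 0 || x < 0 || y > ny - 1 || x > nx - 1) return 0.0;
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  int y1 = std::min(y0 + 1, ny - 1), x1 = std::min(x0 + 1, nx - 1);
  double fy = y - y0, fx = x - x0;
  return (1 - fy) * ((1 - fx) * m(y0, x0) + fx * m(y0, x1)) +
         fy * ((1 - fx) * m(y1, x0) + fx * m(y1, x1));
}

// Line-integral projection of a volume (ny x nx x nz) at one angle.
// Returns an (nz x nx) matrix: detector rows = z slices, columns = s.
// [[Rcpp::export]]
arma::mat cpp_project_volume(const arma::cube& vol, double angle) {
  const int ny = vol.n_rows, nx = vol.n_cols, nz = vol.n_slices;
  const double cy = (ny - 1) / 2.0, cx = (nx - 1) / 2.0;
  const double ca = std::cos(angle), sa = std::sin(angle);
  arma::mat out(nz, nx, arma::fill::zeros);
  for (int iz = 0; iz < nz; ++iz) {
    const arma::mat& sl = vol.slice(iz);
    for (int s = 0; s < nx; ++s) {
      double sp = s - cx, acc = 0.0;
      for (int t = 0; t < ny; ++t) {
        double tp = t - cy;
        double x = cx + sp * ca - tp * sa;
        double y = cy + sp * sa + tp * ca;
        acc += bilinear(sl, y, x);
      }
      out(iz, s) = acc;
    }
  }
  return out;
}

// Backprojection of an (nang x ndet) sinogram onto an (n x n) slice.
// axis_offset shifts the projection of the rotation axis (in pixels) away
// from the detector center. weight multiplies the sum (use pi/nang).
// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& sino, const arma::vec& angles,
                          int n, double weight, double axis_offset) {
  const int nang = sino.n_rows, ndet = sino.n_cols;
  const double c = (n - 1) / 2.0, cdet = (ndet - 1) / 2.0 + axis_offset;
  arma::mat out(n, n, arma::fill::zeros);
  for (int a = 0; a < nang; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int iy = 0; iy < n; ++iy) {
      double yp = iy - c;
      for (int ix = 0; ix < n; ++ix) {
        double xp = ix - c;
        double s = cdet + xp * ca + yp * sa;
        if (s < 0 || s > ndet - 1) continue;
        int s0 = (int)std::floor(s);
        int s1 = std::min(s0 + 1, ndet - 1);
        double fs = s - s0;
        out(iy, ix) += (1 - fs) * sino(a, s0) + fs * sino(a, s1);
      }
    }
  }
  return out * weight;
}

// Windowed median filter with explicit window size and anchor. For pixel
// (i, j) the window spans rows [i - ar, i - ar + kh - 1] and columns
// [j - ac, j - ac + kw - 1], clipped at the image border (truncated
// window). Even windows use the top-left pixel of the central 2x2 block as
// anchor when ar = kh/2 - 1, ac = kw/2 - 1.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, int kh, int kw,
                                int ar, int ac) {
  const int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  std::vector<double> buf;
  buf.reserve(kh * kw);
  for (int i = 0; i < ny; ++i) {
    int r0 = std::max(0, i - ar), r1 = std::min(ny - 1, i - ar + kh - 1);
    for (int j = 0; j < nx; ++j) {
      int c0 = std::max(0, j - ac), c1 = std::min(nx - 1, j - ac + kw - 1);
      buf.clear();
      for (int r = r0; r <= r1; ++r)
        for (int c = c0; c <= c1; ++c) buf.push_back(img(r, c));
      const size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
        med = 0.5 * (med + buf[m - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}
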