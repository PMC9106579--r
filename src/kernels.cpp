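#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 3D connected-component labelling, 26-connectivity.
// `mask` is a logical array (ny, nx, nz); returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = cur / ((R_xlen_t)ny * nx);
      R_xlen_t rem = cur - (R_xlen_t)z * ny * nx;
      int x = rem / ny, y = rem % ny;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            R_xlen_t j = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

static void box1d(const std::vector<double>& v, const std::vector<double>& w,
                  std::vector<double>& ov, std::vector<double>& ow,
                  int n, int stride, int count, R_xlen_t offset, int half) {
  // running box sum of length 2*half+1 along one axis (values + weights)
  for (int i = 0; i < n; ++i) {
    double sv = 0.0, sw = 0.0;
    int lo = i - half, hi = i + half;
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    for (int j = lo; j <= hi; ++j) {
      sv += v[offset + (R_xlen_t)j * stride];
      sw += w[offset + (R_xlen_t)j * stride];
    }
    ov[offset + (R_xlen_t)i * stride] = sv;
    ow[offset + (R_xlen_t)i * stride] = sw;
  }
}

// NA-aware separable 3D box mean with half-widths (hy, hx, hz).
// Returns mean over in-bounds, non-NA voxels of the (2h+1)^3 box.
// [[Rcpp::export]]
NumericVector cpp_boxmean3d(NumericVector arr, IntegerVector dims,
                            int hy, int hx, int hz) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<double> v(n), w(n), v2(n), w2(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (NumericVector::is_na(arr[i])) { v[i] = 0.0; w[i] = 0.0; }
    else { v[i] = arr[i]; w[i] = 1.0; }
  }
  // y axis
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      box1d(v, w, v2, w2, ny, 1, ny, (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny, hy);
  // x axis
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      box1d(v2, w2, v, w, nx, ny, nx, (R_xlen_t)z * ny * nx + y, hx);
  // z axis
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      box1d(v, w, v2, w2, nz, (R_xlen_t)ny * nx, nz, (R_xlen_t)x * ny + y, hz);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = w2[i] > 0 ? v2[i] / w2[i] : NA_REAL;
  out.attr("dim") = dims;
  return out;
}

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int half = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * half + 1);
  double s = 0.0;
  for (int i = -half; i <= half; ++i) {
    k[i + half] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + half];
  }
  for (auto& x : k) x /= s;
  return k;
}

static void conv1d(std::vector<double>& v, std::vector<double>& w,
                   std::vector<double>& tv, std::vector<double>& tw,
                   int n, int stride, R_xlen_t offset,
                   const std::vector<double>& k, bool na_aware) {
  int half = ((int)k.size() - 1) / 2;
  for (int i = 0; i < n; ++i) {
    double sv = 0.0, sw = 0.0;
    for (int j = -half; j <= half; ++j) {
      int p = i + j;
      if (p < 0 || p >= n) continue; // zero padding
      double kv = k[j + half];
      sv += kv * v[offset + (R_xlen_t)p * stride];
      sw += kv * w[offset + (R_xlen_t)p * stride];
    }
    tv[offset + (R_xlen_t)i * stride] = sv;
    tw[offset + (R_xlen_t)i * stride] = sw;
  }
  (void)na_aware;
}

// Separable 3D Gaussian blur with sigmas in pixels (sy, sx, sz).
// na_aware = TRUE renormalizes by the local non-NA kernel mass (for images with
// masked voxels); FALSE is a plain zero-padded convolution that conserves the
// total intensity of interior-supported signal exactly.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector arr, IntegerVector dims,
                          double sy, double sx, double sz, bool na_aware) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<double> v(n), w(n), tv(n), tw(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    bool na = NumericVector::is_na(arr[i]);
    v[i] = na ? 0.0 : arr[i];
    w[i] = na ? 0.0 : 1.0;
  }
  std::vector<double> ky = gauss_kernel(sy), kx = gauss_kernel(sx), kz = gauss_kernel(sz);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      conv1d(v, w, tv, tw, ny, 1, (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny, ky, na_aware);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      conv1d(tv, tw, v, w, nx, ny, (R_xlen_t)z * ny * nx + y, kx, na_aware);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      conv1d(v, w, tv, tw, nz, (R_xlen_t)ny * nx, (R_xlen_t)x * ny + y, kz, na_aware);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (na_aware) out[i] = tw[i] > 1e-12 ? tv[i] / tw[i] : NA_REAL;
    else out[i] = tv[i];
  }
  out.attr("dim") = dims;
  return out;
}

// Binary dilation with a sphere of radius r in voxel (index) units.
// [[Rcpp::export]]
LogicalVector cpp_dilate3d(LogicalVector mask, IntegerVector dims, double r) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  LogicalVector out(n, 0);
  int ri = (int)std::floor(r);
  std::vector<std::array<int,3> > off;
  for (int dz = -ri; dz <= ri; ++dz)
    for (int dx = -ri; dx <= ri; ++dx)
      for (int dy = -ri; dy <= ri; ++dy)
        if ((double)dz*dz + dx*dx + dy*dy <= r * r)
          off.push_back({dy, dx, dz});
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int z = i / ((R_xlen_t)ny * nx);
    R_xlen_t rem = i - (R_xlen_t)z * ny * nx;
    int x = rem / ny, y = rem % ny;
    for (auto& o : off) {
      int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      out[(R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy] = 1;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Rigid in-plane warp of a 2D matrix: the image content is rotated by
// `theta` degrees (counter-clockwise in x-right / y-up convention) about
// (cy, cx) (1-based) and then translated by (ty, tx) pixels. Bilinear
// interpolation; an output pixel is NA if any contributing input pixel is NA
// or out of bounds (mask propagation).
// [[Rcpp::export]]
NumericMatrix cpp_warp2d(NumericMatrix im, double theta, double cy, double cx,
                         double ty, double tx) {
  const int ny = im.nrow(), nx = im.ncol();
  NumericMatrix out(ny, nx);
  const double th = theta * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  for (int c = 0; c < nx; ++c) {
    for (int r = 0; r < ny; ++r) {
      // inverse mapping: undo translation, rotate by -theta about centre.
      double yd = (r + 1) - ty - cy, xd = (c + 1) - tx - cx;
      // y axis points down in matrix convention; CCW rotation in x-right/y-up
      // equals CW in matrix coords, inverse is CCW in matrix coords.
      double xs = ct * xd + st * yd + cx;
      double ys = -st * xd + ct * yd + cy;
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      double fx = xs - x0, fy = ys - y0;
      if (x0 < 1 || y0 < 1 || x0 + 1 > nx || y0 + 1 > ny) {
        out(r, c) = NA_REAL;
        continue;
      }
      double v00 = im(y0 - 1, x0 - 1), v01 = im(y0 - 1, x0);
      double v10 = im(y0, x0 - 1), v11 = im(y0, x0);
      if (NumericMatrix::is_na(v00) || NumericMatrix::is_na(v01) ||
          NumericMatrix::is_na(v10) || NumericMatrix::is_na(v11)) {
        out(r, c) = NA_REAL;
      } else {
        out(r, c) = v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
                    v10 * (1 - fx) * fy + v11 * fx * fy;
      }
    }
  }
  return out;
}
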