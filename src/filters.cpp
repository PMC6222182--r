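// Separable Gaussian-derivative filtering and Hessian-eigenvalue tubularity.
//
// The tube response targets dark tubes (air-filled lumen) on a brighter
// background: with Hessian eigenvalues l1 <= l2 <= l3 of the gamma-normalized
// (gamma = 2) Gaussian-scale Hessian, response = l2*l3 - l1^2 (clipped at 0)
// when l2, l3 > 0, else 0. Derivatives are taken in mm, so anisotropic voxels
// are handled by per-axis kernel scales.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Reflect an index into [0, n).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Sampled Gaussian-derivative kernel (order 0, 1 or 2), sigma in voxels.
// Discretely renormalized so order 0 sums to 1, order 1 differentiates a
// linear ramp exactly, order 2 differentiates a parabola exactly.
static std::vector<double> gauss_kernel(double sigma, int order) {
  int R = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * R + 1);
  double s2 = sigma * sigma;
  for (int i = -R; i <= R; ++i) {
    double g = std::exp(-0.5 * i * i / s2);
    double v;
    if (order == 0) v = g;
    else if (order == 1) v = -(double)i / s2 * g;
    else v = ((double)i * i - s2) / (s2 * s2) * g;
    k[i + R] = v;
  }
  int n = 2 * R + 1;
  if (order == 0) {
    double s = 0.0;
    for (double v : k) s += v;
    for (double& v : k) v /= s;
  } else if (order == 1) {
    double s = 0.0;
    for (double v : k) s += v;
    for (double& v : k) v -= s / n;
    // out[i] = sum_t k[t] f(i + t - R); ramp f = x must give 1
    double m = 0.0;
    for (int t = 0; t < n; ++t) m += k[t] * (t - R);
    for (double& v : k) v /= m;
  } else {
    double s = 0.0;
    for (double v : k) s += v;
    for (double& v : k) v -= s / n;
    double m = 0.0;
    for (int t = 0; t < n; ++t) m += 0.5 * k[t] * (t - R) * (t - R);
    for (double& v : k) v /= m;
  }
  return k;
}

// Convolve one line held in buf[0..n) into out[0..n); reflect boundary with
// a fast interior path (no index arithmetic where the kernel fits).
static inline void conv_line(const double* buf, double* out, int n,
                             const double* kc, int R) {
  int lo = std::min(R, n), hi = std::max(n - R, lo);
  for (int i = 0; i < lo; ++i) {
    double acc = 0.0;
    for (int t = -R; t <= R; ++t) acc += kc[t] * buf[reflect_idx(i + t, n)];
    out[i] = acc;
  }
  for (int i = lo; i < hi; ++i) {
    double acc = 0.0;
    const double* b = buf + i;
    for (int t = -R; t <= R; ++t) acc += kc[t] * b[t];
    out[i] = acc;
  }
  for (int i = hi; i < n; ++i) {
    double acc = 0.0;
    for (int t = -R; t <= R; ++t) acc += kc[t] * buf[reflect_idx(i + t, n)];
    out[i] = acc;
  }
}

// In-place 1D convolution of a 3D volume along one axis, reflect boundary.
static void conv_axis(std::vector<double>& a, const int dim[3], int axis,
                      const std::vector<double>& k) {
  const int R = (int)(k.size() / 2);
  const double* kc = k.data() + R;  // centered kernel
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long sy = nx, sz = (long)nx * ny;
  const int n = dim[axis];
  std::vector<double> buf(n), outl(n);

  if (axis == 0) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        double* line = &a[(long)z * sz + (long)y * sy];
        conv_line(line, outl.data(), n, kc, R);
        for (int i = 0; i < n; ++i) line[i] = outl[i];
      }
  } else if (axis == 1) {
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        double* base = &a[(long)z * sz + x];
        for (int i = 0; i < n; ++i) buf[i] = base[(long)i * sy];
        conv_line(buf.data(), outl.data(), n, kc, R);
        for (int i = 0; i < n; ++i) base[(long)i * sy] = outl[i];
      }
  } else {
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double* base = &a[(long)y * sy + x];
        for (int i = 0; i < n; ++i) buf[i] = base[(long)i * sz];
        conv_line(buf.data(), outl.data(), n, kc, R);
        for (int i = 0; i < n; ++i) base[(long)i * sz] = outl[i];
      }
  }
}

// Eigenvalues of a symmetric 3x3 matrix, ascending (trigonometric method).
static inline void eig3_sym(double a00, double a01, double a02,
                            double a11, double a12, double a22,
                            double w[3]) {
  double p1 = a01 * a01 + a02 * a02 + a12 * a12;
  if (p1 == 0.0) {
    w[0] = a00; w[1] = a11; w[2] = a22;
  } else {
    double q = (a00 + a11 + a22) / 3.0;
    double p2 = (a00 - q) * (a00 - q) + (a11 - q) * (a11 - q) +
                (a22 - q) * (a22 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double b00 = (a00 - q) / p, b01 = a01 / p, b02 = a02 / p;
    double b11 = (a11 - q) / p, b12 = a12 / p, b22 = (a22 - q) / p;
    double detB = b00 * (b11 * b22 - b12 * b12) -
                  b01 * (b01 * b22 - b12 * b02) +
                  b02 * (b01 * b12 - b11 * b02);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    double e1 = q + 2.0 * p * std::cos(phi);                   // largest
    double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0); // smallest
    double e2 = 3.0 * q - e1 - e3;
    w[0] = e3; w[1] = e2; w[2] = e1;
    return;
  }
  // sort the diagonal case
  if (w[0] > w[1]) std::swap(w[0], w[1]);
  if (w[1] > w[2]) std::swap(w[1], w[2]);
  if (w[0] > w[1]) std::swap(w[0], w[1]);
}

// [[Rcpp::export]]
NumericVector cpp_tubularity(NumericVector vol, IntegerVector dims,
                             NumericVector spacing, double sigma_mm) {
  int dim[3] = {dims[0], dims[1], dims[2]};
  long n = (long)dim[0] * dim[1] * dim[2];
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];

  // per-axis kernels at sigma (voxels)
  std::vector<double> k0[3], k1[3], k2[3];
  double sp[3] = {dx, dy, dz};
  for (int a = 0; a < 3; ++a) {
    double sv = sigma_mm / sp[a];
    k0[a] = gauss_kernel(sv, 0);
    k1[a] = gauss_kernel(sv, 1);
    k2[a] = gauss_kernel(sv, 2);
  }

  std::vector<double> base(vol.begin(), vol.end());

  // x-stage
  std::vector<double> Sx0(base), Sx1(base), Sx2(base);
  conv_axis(Sx0, dim, 0, k0[0]);
  conv_axis(Sx1, dim, 0, k1[0]);
  conv_axis(Sx2, dim, 0, k2[0]);
  std::vector<double>().swap(base);

  // y-stage (reuse buffers where possible)
  std::vector<double> Dxx(Sx2); conv_axis(Dxx, dim, 1, k0[1]);
  std::vector<double>().swap(Sx2);
  std::vector<double> Dxy(Sx1); conv_axis(Dxy, dim, 1, k1[1]);
  std::vector<double> Dxz(Sx1); conv_axis(Dxz, dim, 1, k0[1]);
  std::vector<double>().swap(Sx1);
  std::vector<double> Dyy(Sx0); conv_axis(Dyy, dim, 1, k2[1]);
  std::vector<double> Dyz(Sx0); conv_axis(Dyz, dim, 1, k1[1]);
  std::vector<double> Dzz(Sx0); conv_axis(Dzz, dim, 1, k0[1]);
  std::vector<double>().swap(Sx0);

  // z-stage
  conv_axis(Dxx, dim, 2, k0[2]);
  conv_axis(Dxy, dim, 2, k0[2]);
  conv_axis(Dxz, dim, 2, k1[2]);
  conv_axis(Dyy, dim, 2, k0[2]);
  conv_axis(Dyz, dim, 2, k1[2]);
  conv_axis(Dzz, dim, 2, k2[2]);

  // unit conversion (voxel -> mm) and gamma=2 normalization (sigma^2)
  double g = sigma_mm * sigma_mm;
  double cxx = g / (dx * dx), cyy = g / (dy * dy), czz = g / (dz * dz);
  double cxy = g / (dx * dy), cxz = g / (dx * dz), cyz = g / (dy * dz);

  NumericVector out(n);
  double w[3];
  for (long i = 0; i < n; ++i) {
    eig3_sym(Dxx[i] * cxx, Dxy[i] * cxy, Dxz[i] * cxz,
             Dyy[i] * cyy, Dyz[i] * cyz, Dzz[i] * czz, w);
    double r = 0.0;
    if (w[1] > 0.0 && w[2] > 0.0) {
      r = w[1] * w[2] - w[0] * w[0];
      if (r < 0.0) r = 0.0;
    }
    out[i] = r;
  }
  out.attr("dim") = dims;
  return out;
}

// Gaussian smoothing only (used by tests and surface extraction helpers).
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dims,
                                  NumericVector sigma_vox) {
  int dim[3] = {dims[0], dims[1], dims[2]};
  std::vector<double> a(vol.begin(), vol.end());
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma_vox[ax] > 0) {
      std::vector<double> k = gauss_kernel(sigma_vox[ax], 0);
      conv_axis(a, dim, ax, k);
    }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
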