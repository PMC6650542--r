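#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Index helper: voxel (i,j,k), 0-based, dims (nx,ny,nz), x fastest.
static inline int vidx(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Mirror (reflecting) boundary index.
static inline int mirror(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static void conv1d_axis(std::vector<double> &src, std::vector<double> &dst,
                        int nx, int ny, int nz, int axis,
                        const std::vector<double> &kern) {
  int r = (int)(kern.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  int na = n[axis];
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int c[3] = {i, j, k};
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int cc[3] = {i, j, k};
          cc[axis] = mirror(c[axis] + t, na);
          acc += kern[t + r] * src[vidx(cc[0], cc[1], cc[2], nx, ny)];
        }
        dst[vidx(i, j, k, nx, ny)] = acc;
      }
    }
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    double v = std::exp(-0.5 * (t * t) / (sigma * sigma));
    kern[t + r] = v;
    s += v;
  }
  for (size_t m = 0; m < kern.size(); ++m) kern[m] /= s;
  return kern;
}

// Separable Gaussian blur; sigma given in voxels per axis (0 = skip axis).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3(NumericVector img, IntegerVector dim,
                                 NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(img.begin(), img.end()), b(n);
  for (int axis = 0; axis < 3; ++axis) {
    if (sigma[axis] <= 0) continue;
    std::vector<double> kern = gauss_kernel(sigma[axis]);
    conv1d_axis(a, b, nx, ny, nz, axis, kern);
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Perona-Malik diffusion on the 6-neighborhood, exponential conductance
// g(d) = exp(-(d/kappa)^2), explicit scheme I += lambda * sum g(d) d with
// zero-flux boundaries (conserves total intensity).
// [[Rcpp::export]]
NumericVector cpp_perona_malik3(NumericVector img, IntegerVector dim,
                                double kappa, double lambda, int iters) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(img.begin(), img.end()), b(n);
  const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  double inv_k2 = 1.0 / (kappa * kappa);
  for (int it = 0; it < iters; ++it) {
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          double c = a[vidx(i, j, k, nx, ny)];
          double flux = 0.0;
          for (int d = 0; d < 6; ++d) {
            int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;  // zero flux across the boundary
            double g = a[vidx(ii, jj, kk, nx, ny)] - c;
            flux += std::exp(-(g * g) * inv_k2) * g;
          }
          b[vidx(i, j, k, nx, ny)] = c + lambda * flux;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Central-difference second derivative along `axis` of a (pre-smoothed)
// volume, in physical units (spacing um per axis).
// [[Rcpp::export]]
NumericVector cpp_deriv2(NumericVector img, IntegerVector dim, int axis1,
                         int axis2, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n[3] = {nx, ny, nz};
  size_t ntot = (size_t)nx * ny * nz;
  NumericVector out(ntot);
  double h1 = spacing[axis1], h2 = spacing[axis2];
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int c[3] = {i, j, k};
        double v;
        if (axis1 == axis2) {
          int p[3] = {i, j, k}, m[3] = {i, j, k};
          p[axis1] = mirror(c[axis1] + 1, n[axis1]);
          m[axis1] = mirror(c[axis1] - 1, n[axis1]);
          v = (img[vidx(p[0], p[1], p[2], nx, ny)] -
               2.0 * img[vidx(i, j, k, nx, ny)] +
               img[vidx(m[0], m[1], m[2], nx, ny)]) / (h1 * h1);
        } else {
          int pp[3] = {i, j, k}, pm[3] = {i, j, k}, mp[3] = {i, j, k},
              mm[3] = {i, j, k};
          pp[axis1] = mirror(c[axis1] + 1, n[axis1]);
          pp[axis2] = mirror(c[axis2] + 1, n[axis2]);
          pm[axis1] = mirror(c[axis1] + 1, n[axis1]);
          pm[axis2] = mirror(c[axis2] - 1, n[axis2]);
          mp[axis1] = mirror(c[axis1] - 1, n[axis1]);
          mp[axis2] = mirror(c[axis2] + 1, n[axis2]);
          mm[axis1] = mirror(c[axis1] - 1, n[axis1]);
          mm[axis2] = mirror(c[axis2] - 1, n[axis2]);
          v = (img[vidx(pp[0], pp[1], pp[2], nx, ny)] -
               img[vidx(pm[0], pm[1], pm[2], nx, ny)] -
               img[vidx(mp[0], mp[1], mp[2], nx, ny)] +
               img[vidx(mm[0], mm[1], mm[2], nx, ny)]) / (4.0 * h1 * h2);
        }
        out[vidx(i, j, k, nx, ny)] = v;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Frangi vesselness for bright tubes from the 6 Hessian components.
// Eigenvalues sorted |l1| <= |l2| <= |l3|; response zero unless l2,l3 < 0.
// [[Rcpp::export]]
NumericVector cpp_vesselness(NumericVector hxx, NumericVector hyy,
                             NumericVector hzz, NumericVector hxy,
                             NumericVector hxz, NumericVector hyz,
                             double alpha, double beta, double c) {
  size_t n = hxx.size();
  NumericVector out(n);
  double a2 = 2.0 * alpha * alpha, b2 = 2.0 * beta * beta, c2 = 2.0 * c * c;
  for (size_t v = 0; v < n; ++v) {
    double A = hxx[v], B = hyy[v], C = hzz[v];
    double D = hxy[v], E = hxz[v], F = hyz[v];
    // analytic eigenvalues of symmetric 3x3 (trigonometric method)
    double p1 = D * D + E * E + F * F;
    double l1, l2, l3;
    if (p1 < 1e-30) {
      l1 = A; l2 = B; l3 = C;
    } else {
      double q = (A + B + C) / 3.0;
      double p2 = (A - q) * (A - q) + (B - q) * (B - q) + (C - q) * (C - q) +
                  2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      double b11 = (A - q) / p, b22 = (B - q) / p, b33 = (C - q) / p;
      double b12 = D / p, b13 = E / p, b23 = F / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      double e1 = q + 2.0 * p * std::cos(phi);
      double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      double e2 = 3.0 * q - e1 - e3;
      l1 = e1; l2 = e2; l3 = e3;
    }
    // sort by absolute value
    double ev[3] = {l1, l2, l3};
    for (int s = 0; s < 2; ++s)
      for (int t = 0; t < 2 - s; ++t)
        if (std::fabs(ev[t]) > std::fabs(ev[t + 1])) std::swap(ev[t], ev[t + 1]);
    l1 = ev[0]; l2 = ev[1]; l3 = ev[2];
    if (l2 >= 0 || l3 >= 0) { out[v] = 0.0; continue; }
    double Ra = std::fabs(l2) / std::fabs(l3);
    double Rb = std::fabs(l1) / std::sqrt(std::fabs(l2 * l3));
    double S2 = l1 * l1 + l2 * l2 + l3 * l3;
    double V = (1.0 - std::exp(-(Ra * Ra) / a2)) *
               std::exp(-(Rb * Rb) / b2) *
               (1.0 - std::exp(-S2 / c2));
    out[v] = V;
  }
  return out;
}
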