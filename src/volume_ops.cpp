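// Dense 3D volume primitives for registration, label mapping and
// postprocessing: trilinear/nearest warping through affine + displacement,
// displacement-field inversion and residuals, separable Gaussian smoothing,
// finite-difference gradients and Jacobians, trilinear resize and
// 26-connected component labelling. Double precision; coordinates 0-based.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::uword;

static cube cube_from_R(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  cube x(d[0], d[1], d[2]);
  std::copy(a.begin(), a.end(), x.memptr());
  return x;
}

static NumericVector cube_to_R(const cube& x) {
  NumericVector out(x.n_elem);
  std::copy(x.memptr(), x.memptr() + x.n_elem, out.begin());
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

static inline double sample_trilinear(const cube& v, double x, double y,
                                      double z, double fill) {
  const int d1 = v.n_rows, d2 = v.n_cols, d3 = v.n_slices;
  if (x < 0 || y < 0 || z < 0 || x > d1 - 1 || y > d2 - 1 || z > d3 - 1)
    return fill;
  int x0 = std::min((int)x, d1 - 2 < 0 ? 0 : d1 - 2);
  int y0 = std::min((int)y, d2 - 2 < 0 ? 0 : d2 - 2);
  int z0 = std::min((int)z, d3 - 2 < 0 ? 0 : d3 - 2);
  const int x1 = std::min(x0 + 1, d1 - 1), y1 = std::min(y0 + 1, d2 - 1),
            z1 = std::min(z0 + 1, d3 - 1);
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const double c00 = v(x0, y0, z0) * (1 - fx) + v(x1, y0, z0) * fx;
  const double c10 = v(x0, y1, z0) * (1 - fx) + v(x1, y1, z0) * fx;
  const double c01 = v(x0, y0, z1) * (1 - fx) + v(x1, y0, z1) * fx;
  const double c11 = v(x0, y1, z1) * (1 - fx) + v(x1, y1, z1) * fx;
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz;
}

static inline double sample_nearest(const cube& v, double x, double y,
                                    double z, double fill) {
  const int i = (int)std::lround(x), j = (int)std::lround(y),
            k = (int)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= (int)v.n_rows || j >= (int)v.n_cols ||
      k >= (int)v.n_slices)
    return fill;
  return v(i, j, k);
}

// clamped trilinear (for sampling displacement fields near the border)
static inline double sample_clamped(const cube& v, double x, double y, double z) {
  x = std::min(std::max(x, 0.0), (double)v.n_rows - 1);
  y = std::min(std::max(y, 0.0), (double)v.n_cols - 1);
  z = std::min(std::max(z, 0.0), (double)v.n_slices - 1);
  return sample_trilinear(v, x, y, z, 0.0);
}

// out(x) = vol( A %*% c(x + u(x), 1) ), A a 3x4 matrix, u optional.
// [[Rcpp::export]]
NumericVector cpp_warp_volume(NumericVector vol, NumericMatrix affine,
                              Nullable<List> disp, IntegerVector out_dim,
                              bool nearest = false, double fill = 0.0) {
  cube v = cube_from_R(vol);
  const int d1 = out_dim[0], d2 = out_dim[1], d3 = out_dim[2];
  cube u1, u2, u3;
  bool has_disp = disp.isNotNull();
  if (has_disp) {
    List d(disp);
    u1 = cube_from_R(d[0]); u2 = cube_from_R(d[1]); u3 = cube_from_R(d[2]);
    if ((int)u1.n_rows != d1 || (int)u1.n_cols != d2 || (int)u1.n_slices != d3)
      stop("displacement field shape must match the output grid");
  }
  cube out(d1, d2, d3);
  const double a11 = affine(0,0), a12 = affine(0,1), a13 = affine(0,2), a14 = affine(0,3);
  const double a21 = affine(1,0), a22 = affine(1,1), a23 = affine(1,2), a24 = affine(1,3);
  const double a31 = affine(2,0), a32 = affine(2,1), a33 = affine(2,2), a34 = affine(2,3);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double x = i, y = j, z = k;
        if (has_disp) { x += u1(i,j,k); y += u2(i,j,k); z += u3(i,j,k); }
        const double px = a11*x + a12*y + a13*z + a14;
        const double py = a21*x + a22*y + a23*z + a24;
        const double pz = a31*x + a32*y + a33*z + a34;
        out(i,j,k) = nearest ? sample_nearest(v, px, py, pz, fill)
                             : sample_trilinear(v, px, py, pz, fill);
      }
  return cube_to_R(out);
}

// fixed-point inversion of x -> x + u(x): v_{n+1}(x) = -u(x + v_n(x))
// [[Rcpp::export]]
List cpp_invert_field(List disp, int iters = 8) {
  cube u1 = cube_from_R(disp[0]), u2 = cube_from_R(disp[1]),
       u3 = cube_from_R(disp[2]);
  cube v1(arma::size(u1), arma::fill::zeros), v2 = v1, v3 = v1;
  for (int it = 0; it < iters; ++it) {
    cube n1 = v1, n2 = v2, n3 = v3;
    for (uword k = 0; k < u1.n_slices; ++k)
      for (uword j = 0; j < u1.n_cols; ++j)
        for (uword i = 0; i < u1.n_rows; ++i) {
          const double x = i + v1(i,j,k), y = j + v2(i,j,k), z = k + v3(i,j,k);
          n1(i,j,k) = -sample_clamped(u1, x, y, z);
          n2(i,j,k) = -sample_clamped(u2, x, y, z);
          n3(i,j,k) = -sample_clamped(u3, x, y, z);
        }
    v1 = n1; v2 = n2; v3 = n3;
  }
  return List::create(cube_to_R(v1), cube_to_R(v2), cube_to_R(v3));
}

// mean | u(x + v(x)) + v(x) | over the grid (composition residual, voxels)
// [[Rcpp::export]]
double cpp_field_residual(List u, List v) {
  cube u1 = cube_from_R(u[0]), u2 = cube_from_R(u[1]), u3 = cube_from_R(u[2]);
  cube v1 = cube_from_R(v[0]), v2 = cube_from_R(v[1]), v3 = cube_from_R(v[2]);
  double acc = 0.0;
  for (uword k = 0; k < u1.n_slices; ++k)
    for (uword j = 0; j < u1.n_cols; ++j)
      for (uword i = 0; i < u1.n_rows; ++i) {
        const double x = i + v1(i,j,k), y = j + v2(i,j,k), z = k + v3(i,j,k);
        const double r1 = sample_clamped(u1, x, y, z) + v1(i,j,k);
        const double r2 = sample_clamped(u2, x, y, z) + v2(i,j,k);
        const double r3 = sample_clamped(u3, x, y, z) + v3(i,j,k);
        acc += std::sqrt(r1*r1 + r2*r2 + r3*r3);
      }
  return acc / u1.n_elem;
}

static void gauss1d(const std::vector<double>& in, std::vector<double>& out,
                    const std::vector<double>& kern) {
  const int n = in.size(), r = (kern.size() - 1) / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = -r; t <= r; ++t) {
      int idx = i + t;
      if (idx < 0) idx = -idx;                    // reflect
      if (idx >= n) idx = 2 * n - 2 - idx;
      if (idx < 0) idx = 0;
      acc += in[idx] * kern[t + r];
    }
    out[i] = acc;
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) s += (k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma)));
  for (double& v : k) v /= s;
  return k;
}

// separable Gaussian smoothing with reflecting boundaries; sigma per axis
// (voxels); sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector vol, NumericVector sigma) {
  cube v = cube_from_R(vol);
  const int d1 = v.n_rows, d2 = v.n_cols, d3 = v.n_slices;
  if (sigma[0] > 0 && d1 > 1) {
    std::vector<double> kern = gauss_kernel(sigma[0]), in(d1), out(d1);
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j) {
        for (int i = 0; i < d1; ++i) in[i] = v(i,j,k);
        gauss1d(in, out, kern);
        for (int i = 0; i < d1; ++i) v(i,j,k) = out[i];
      }
  }
  if (sigma[1] > 0 && d2 > 1) {
    std::vector<double> kern = gauss_kernel(sigma[1]), in(d2), out(d2);
    for (int k = 0; k < d3; ++k)
      for (int i = 0; i < d1; ++i) {
        for (int j = 0; j < d2; ++j) in[j] = v(i,j,k);
        gauss1d(in, out, kern);
        for (int j = 0; j < d2; ++j) v(i,j,k) = out[j];
      }
  }
  if (sigma[2] > 0 && d3 > 1) {
    std::vector<double> kern = gauss_kernel(sigma[2]), in(d3), out(d3);
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        for (int k = 0; k < d3; ++k) in[k] = v(i,j,k);
        gauss1d(in, out, kern);
        for (int k = 0; k < d3; ++k) v(i,j,k) = out[k];
      }
  }
  return cube_to_R(v);
}

// central-difference gradient (one-sided at borders), per axis
// [[Rcpp::export]]
List cpp_gradient3d(NumericVector vol) {
  cube v = cube_from_R(vol);
  const int d1 = v.n_rows, d2 = v.n_cols, d3 = v.n_slices;
  cube g1(d1,d2,d3, arma::fill::zeros), g2 = g1, g3 = g1;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        if (d1 > 1) {
          const int ip = std::min(i+1, d1-1), im = std::max(i-1, 0);
          g1(i,j,k) = (v(ip,j,k) - v(im,j,k)) / (ip - im);
        }
        if (d2 > 1) {
          const int jp = std::min(j+1, d2-1), jm = std::max(j-1, 0);
          g2(i,j,k) = (v(i,jp,k) - v(i,jm,k)) / (jp - jm);
        }
        if (d3 > 1) {
          const int kp = std::min(k+1, d3-1), km = std::max(k-1, 0);
          g3(i,j,k) = (v(i,j,kp) - v(i,j,km)) / (kp - km);
        }
      }
  return List::create(cube_to_R(g1), cube_to_R(g2), cube_to_R(g3));
}

// Jacobian determinant statistics of x -> x + u(x) (central differences on
// the interior): returns (min det, fraction of dets <= 0)
// [[Rcpp::export]]
NumericVector cpp_jacobian_stats(List disp) {
  cube u1 = cube_from_R(disp[0]), u2 = cube_from_R(disp[1]),
       u3 = cube_from_R(disp[2]);
  const int d1 = u1.n_rows, d2 = u1.n_cols, d3 = u1.n_slices;
  double mind = R_PosInf; double nneg = 0, ntot = 0;
  auto D = [&](const cube& u, int i, int j, int k, int axis) {
    if (axis == 0) {
      const int p = std::min(i+1, d1-1), m = std::max(i-1, 0);
      return p == m ? 0.0 : (u(p,j,k) - u(m,j,k)) / (p - m);
    } else if (axis == 1) {
      const int p = std::min(j+1, d2-1), m = std::max(j-1, 0);
      return p == m ? 0.0 : (u(i,p,k) - u(i,m,k)) / (p - m);
    }
    const int p = std::min(k+1, d3-1), m = std::max(k-1, 0);
    return p == m ? 0.0 : (u(i,j,p) - u(i,j,m)) / (p - m);
  };
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const double j11 = 1 + D(u1,i,j,k,0), j12 = D(u1,i,j,k,1), j13 = D(u1,i,j,k,2);
        const double j21 = D(u2,i,j,k,0), j22 = 1 + D(u2,i,j,k,1), j23 = D(u2,i,j,k,2);
        const double j31 = D(u3,i,j,k,0), j32 = D(u3,i,j,k,1), j33 = 1 + D(u3,i,j,k,2);
        const double det = j11*(j22*j33 - j23*j32) - j12*(j21*j33 - j23*j31)
                         + j13*(j21*j32 - j22*j31);
        mind = std::min(mind, det);
        if (det <= 0) nneg += 1;
        ntot += 1;
      }
  return NumericVector::create(mind, nneg / ntot);
}

// trilinear resize to new dims (align-corners coordinate mapping)
// [[Rcpp::export]]
NumericVector cpp_resize3d(NumericVector vol, IntegerVector new_dim,
                           bool nearest = false) {
  cube v = cube_from_R(vol);
  const int n1 = new_dim[0], n2 = new_dim[1], n3 = new_dim[2];
  const double s1 = n1 > 1 ? (double)(v.n_rows - 1) / (n1 - 1) : 0.0;
  const double s2 = n2 > 1 ? (double)(v.n_cols - 1) / (n2 - 1) : 0.0;
  const double s3 = n3 > 1 ? (double)(v.n_slices - 1) / (n3 - 1) : 0.0;
  cube out(n1, n2, n3);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i)
        out(i,j,k) = nearest
          ? sample_nearest(v, i*s1, j*s2, k*s3, 0.0)
          : sample_trilinear(v, i*s1, j*s2, k*s3, 0.0);
  return cube_to_R(out);
}

// 26-connected component labelling of a binary volume (BFS);
// returns integer label volume (0 = background) and component sizes
// [[Rcpp::export]]
List cpp_label3d(NumericVector vol) {
  cube v = cube_from_R(vol);
  const int d1 = v.n_rows, d2 = v.n_cols, d3 = v.n_slices;
  arma::icube lab(d1, d2, d3, arma::fill::zeros);
  std::vector<int> sizes;
  std::vector<long long> q;
  int next = 0;
  for (int k0 = 0; k0 < d3; ++k0)
    for (int j0 = 0; j0 < d2; ++j0)
      for (int i0 = 0; i0 < d1; ++i0) {
        if (v(i0,j0,k0) == 0 || lab(i0,j0,k0) != 0) continue;
        ++next;
        int sz = 0;
        q.clear();
        lab(i0,j0,k0) = next;
        q.push_back(i0 + (long long)d1 * (j0 + (long long)d2 * k0));
        size_t head = 0;
        while (head < q.size()) {
          const long long idx = q[head++];
          ++sz;
          const int i = idx % d1, j = (idx / d1) % d2, k = idx / ((long long)d1 * d2);
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (!di && !dj && !dk) continue;
                const int ii = i+di, jj = j+dj, kk = k+dk;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
                  continue;
                if (v(ii,jj,kk) != 0 && lab(ii,jj,kk) == 0) {
                  lab(ii,jj,kk) = next;
                  q.push_back(ii + (long long)d1 * (jj + (long long)d2 * kk));
                }
              }
        }
        sizes.push_back(sz);
      }
  IntegerVector labR(lab.n_elem);
  std::copy(lab.memptr(), lab.memptr() + lab.n_elem, labR.begin());
  labR.attr("dim") = IntegerVector::create(d1, d2, d3);
  return List::create(_["labels"] = labR,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}
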