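#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Physical coordinate of 0-based voxel index i on an n-grid with the box
// centre at voxel n/2: x = (i - n/2) * apix.

static inline int wrap_idx(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// Rasterize Gaussian blobs on a 2D grid. centers in Angstrom relative to
// the image centre; value w * exp(-r^2 / (2 sd^2)), truncated at 4.5 sd.
// [[Rcpp::export]]
NumericMatrix cpp_render_gauss2d(NumericMatrix centers, NumericVector sd,
                                 NumericVector w, int n, double apix) {
  NumericMatrix img(n, n);
  const int c = n / 2;
  for (int b = 0; b < centers.nrow(); ++b) {
    const double cx = centers(b, 0), cy = centers(b, 1);
    const double s = sd[b], wt = w[b];
    const double cut = 4.5 * s;
    const double inv2s2 = 1.0 / (2.0 * s * s);
    int i0 = (int)std::floor((cx - cut) / apix) + c;
    int i1 = (int)std::ceil((cx + cut) / apix) + c;
    int j0 = (int)std::floor((cy - cut) / apix) + c;
    int j1 = (int)std::ceil((cy + cut) / apix) + c;
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0;
    if (i1 > n - 1) i1 = n - 1; if (j1 > n - 1) j1 = n - 1;
    for (int j = j0; j <= j1; ++j) {
      const double dy = (j - c) * apix - cy;
      for (int i = i0; i <= i1; ++i) {
        const double dx = (i - c) * apix - cx;
        const double r2 = dx * dx + dy * dy;
        img(i, j) += wt * std::exp(-r2 * inv2s2);
      }
    }
  }
  return img;
}

// Stack variant: blob b belongs to image img_index[b] (1-based).
// Returns an (n*n) x N matrix, one column per image.
// [[Rcpp::export]]
NumericMatrix cpp_render_gauss2d_stack(NumericMatrix centers, NumericVector sd,
                                       NumericVector w, IntegerVector img_index,
                                       int n, double apix, int nimg) {
  NumericMatrix out(n * n, nimg);
  const int c = n / 2;
  for (int b = 0; b < centers.nrow(); ++b) {
    const int p = img_index[b] - 1;
    const double cx = centers(b, 0), cy = centers(b, 1);
    const double s = sd[b], wt = w[b];
    const double cut = 4.5 * s;
    const double inv2s2 = 1.0 / (2.0 * s * s);
    int i0 = (int)std::floor((cx - cut) / apix) + c;
    int i1 = (int)std::ceil((cx + cut) / apix) + c;
    int j0 = (int)std::floor((cy - cut) / apix) + c;
    int j1 = (int)std::ceil((cy + cut) / apix) + c;
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0;
    if (i1 > n - 1) i1 = n - 1; if (j1 > n - 1) j1 = n - 1;
    double *col = &out(0, p);
    for (int j = j0; j <= j1; ++j) {
      const double dy = (j - c) * apix - cy;
      for (int i = i0; i <= i1; ++i) {
        const double dx = (i - c) * apix - cx;
        col[i + n * j] += wt * std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
  return out;
}

// Rasterize Gaussian blobs on a 3D grid (same conventions as 2D).
// [[Rcpp::export]]
NumericVector cpp_render_gauss3d(NumericMatrix centers, NumericVector sd,
                                 NumericVector w, int n, double apix) {
  NumericVector vol(n * n * n);
  const int c = n / 2;
  for (int b = 0; b < centers.nrow(); ++b) {
    const double cx = centers(b, 0), cy = centers(b, 1), cz = centers(b, 2);
    const double s = sd[b], wt = w[b];
    const double cut = 4.5 * s;
    const double inv2s2 = 1.0 / (2.0 * s * s);
    int i0 = std::max(0, (int)std::floor((cx - cut) / apix) + c);
    int i1 = std::min(n - 1, (int)std::ceil((cx + cut) / apix) + c);
    int j0 = std::max(0, (int)std::floor((cy - cut) / apix) + c);
    int j1 = std::min(n - 1, (int)std::ceil((cy + cut) / apix) + c);
    int k0 = std::max(0, (int)std::floor((cz - cut) / apix) + c);
    int k1 = std::min(n - 1, (int)std::ceil((cz + cut) / apix) + c);
    for (int k = k0; k <= k1; ++k) {
      const double dz = (k - c) * apix - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = (j - c) * apix - cy;
        const double base = dz * dz + dy * dy;
        for (int i = i0; i <= i1; ++i) {
          const double dx = (i - c) * apix - cx;
          vol[i + n * (j + n * k)] += wt * std::exp(-(dx * dx + base) * inv2s2);
        }
      }
    }
  }
  vol.attr("dim") = IntegerVector::create(n, n, n);
  return vol;
}

// Extract central sections from the FFT of a (padded, centre-at-origin)
// volume. vhat: complex pn^3 array in FFT index order, DC at [0,0,0],
// corresponding to a real-space volume circularly shifted so the box centre
// sits at index 0. rots: 9 x N matrix, column p = rotation matrix R_p
// (column-major) with image = R %*% volume point. The slice is sampled at
// q = pad * R^T f for integer image frequencies f=(fx,fy,0) on the n_out
// grid, trilinear, zero outside the |f| <= n_out/2 circle.
// [[Rcpp::export]]
ComplexMatrix cpp_fourier_slice(ComplexVector vhat, NumericMatrix rots,
                                int pn, int n_out, int pad) {
  const int np = rots.ncol();
  ComplexMatrix out(n_out * n_out, np);
  const double fmax = n_out / 2.0;
  const Rcomplex *V = vhat.begin();
  for (int p = 0; p < np; ++p) {
    const double *R = &rots(0, p);
    Rcomplex *col = &out(0, p);
    for (int jy = 0; jy < n_out; ++jy) {
      int fy = jy <= n_out / 2 ? jy : jy - n_out;
      for (int jx = 0; jx < n_out; ++jx) {
        int fx = jx <= n_out / 2 ? jx : jx - n_out;
        Rcomplex val; val.r = 0.0; val.i = 0.0;
        if ((double)(fx * fx + fy * fy) <= fmax * fmax) {
          // q = pad * R^T f ; R column-major: R[i + 3j] = R(i,j)
          const double qx = pad * (R[0] * fx + R[1] * fy);
          const double qy = pad * (R[3] * fx + R[4] * fy);
          const double qz = pad * (R[6] * fx + R[7] * fy);
          const int x0 = (int)std::floor(qx), y0 = (int)std::floor(qy),
                    z0 = (int)std::floor(qz);
          const double tx = qx - x0, ty = qy - y0, tz = qz - z0;
          for (int dz = 0; dz < 2; ++dz) {
            const double wz = dz ? tz : 1.0 - tz;
            const int kz = wrap_idx(z0 + dz, pn);
            for (int dy = 0; dy < 2; ++dy) {
              const double wy = dy ? ty : 1.0 - ty;
              const int ky = wrap_idx(y0 + dy, pn);
              const double wyz = wy * wz;
              for (int dx = 0; dx < 2; ++dx) {
                const double wt = (dx ? tx : 1.0 - tx) * wyz;
                const int kx = wrap_idx(x0 + dx, pn);
                const Rcomplex &v = V[kx + (size_t)pn * (ky + (size_t)pn * kz)];
                val.r += wt * v.r;
                val.i += wt * v.i;
              }
            }
          }
        }
        col[jx + n_out * jy] = val;
      }
    }
  }
  return out;
}

// Adjoint of cpp_fourier_slice: spread CTF- and weight-multiplied image
// transforms into the padded Fourier accumulator. slices: FT of images
// (n_out^2 x N, shift/centre phases already applied); ctf: same shape;
// wts: per-particle weights. acc_re/acc_im/acc_w (each pn^3) are modified
// in place: acc += trilinear(ctf * slice * w) and acc_w += trilinear(
// ctf^2 * w).
// [[Rcpp::export]]
void cpp_backproject_insert(ComplexMatrix slices, NumericMatrix ctf,
                            NumericVector wts, NumericMatrix rots,
                            int pn, int n_out, int pad,
                            NumericVector acc_re, NumericVector acc_im,
                            NumericVector acc_w) {
  const int np = rots.ncol();
  const double fmax = n_out / 2.0;
  double *AR = acc_re.begin(), *AI = acc_im.begin(), *AW = acc_w.begin();
  for (int p = 0; p < np; ++p) {
    const double wpart = wts[p];
    if (wpart == 0.0) continue;
    const double *R = &rots(0, p);
    const Rcomplex *col = &slices(0, p);
    const double *ccol = &ctf(0, p);
    for (int jy = 0; jy < n_out; ++jy) {
      int fy = jy <= n_out / 2 ? jy : jy - n_out;
      for (int jx = 0; jx < n_out; ++jx) {
        int fx = jx <= n_out / 2 ? jx : jx - n_out;
        if ((double)(fx * fx + fy * fy) > fmax * fmax) continue;
        const int px = jx + n_out * jy;
        const double cv = ccol[px];
        const double dr = col[px].r * cv * wpart;
        const double di = col[px].i * cv * wpart;
        const double dw = cv * cv * wpart;
        const double qx = pad * (R[0] * fx + R[1] * fy);
        const double qy = pad * (R[3] * fx + R[4] * fy);
        const double qz = pad * (R[6] * fx + R[7] * fy);
        const int x0 = (int)std::floor(qx), y0 = (int)std::floor(qy),
                  z0 = (int)std::floor(qz);
        const double tx = qx - x0, ty = qy - y0, tz = qz - z0;
        for (int dz = 0; dz < 2; ++dz) {
          const double wz = dz ? tz : 1.0 - tz;
          const int kz = wrap_idx(z0 + dz, pn);
          for (int dy = 0; dy < 2; ++dy) {
            const double wyz = (dy ? ty : 1.0 - ty) * wz;
            const int ky = wrap_idx(y0 + dy, pn);
            for (int dx = 0; dx < 2; ++dx) {
              const double wt = (dx ? tx : 1.0 - tx) * wyz;
              const size_t idx =
                  wrap_idx(x0 + dx, pn) + (size_t)pn * (ky + (size_t)pn * kz);
              AR[idx] += wt * dr;
              AI[idx] += wt * di;
              AW[idx] += wt * dw;
            }
          }
        }
      }
    }
  }
}

// Trilinear sampling of a cubic volume at voxel coordinates (0-based).
// Points outside the grid return NA.
// [[Rcpp::export]]
NumericVector cpp_trilinear_sample(NumericVector vol, int n, NumericMatrix pts) {
  const int np = pts.nrow();
  NumericVector out(np);
  const double *V = vol.begin();
  for (int p = 0; p < np; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > n - 1 || y > n - 1 || z > n - 1) {
      out[p] = NA_REAL;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == n - 1) x0--;
    if (y0 == n - 1) y0--;
    if (z0 == n - 1) z0--;
    const double tx = x - x0, ty = y - y0, tz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
      const double wz = dz ? tz : 1.0 - tz;
      for (int dy = 0; dy < 2; ++dy) {
        const double wyz = (dy ? ty : 1.0 - ty) * wz;
        for (int dx = 0; dx < 2; ++dx) {
          const double wt = (dx ? tx : 1.0 - tx) * wyz;
          acc += wt * V[(x0 + dx) + (size_t)n * ((y0 + dy) + (size_t)n * (z0 + dz))];
        }
      }
    }
    out[p] = acc;
  }
  return out;
}

// Real-space screw averaging: out(x) = mean over k in [kmin, kmax] of
// vol(S_k^{-1} x), S_k = rotation by k*twist about z then translation by
// k*rise along z; only source points whose z lies within the central
// zfrac of the box contribute. Helical axis = z through the box centre.
// [[Rcpp::export]]
NumericVector cpp_screw_average(NumericVector vol, int n, double apix,
                                double rise, double twist_deg,
                                int kmin, int kmax, double zfrac) {
  NumericVector out(n * n * n);
  const int c = n / 2;
  const double zlim = 0.5 * zfrac * n * apix;
  const double *V = vol.begin();
  double *O = out.begin();
  std::vector<double> counts((size_t)n * n * n, 0.0);
  for (int k = kmin; k <= kmax; ++k) {
    const double ang = -k * twist_deg * M_PI / 180.0; // inverse rotation
    const double ca = std::cos(ang), sa = std::sin(ang);
    const double dz_src = -k * rise;                  // inverse translation
    for (int kz = 0; kz < n; ++kz) {
      const double z = (kz - c) * apix;
      const double zs = z + dz_src;
      if (zs < -zlim || zs > zlim) continue;
      const double gz = zs / apix + c;
      if (gz < 0 || gz > n - 1) continue;
      for (int jy = 0; jy < n; ++jy) {
        const double y = (jy - c) * apix;
        for (int ix = 0; ix < n; ++ix) {
          const double x = (ix - c) * apix;
          const double xs = ca * x - sa * y;
          const double ys = sa * x + ca * y;
          const double gx = xs / apix + c;
          const double gy = ys / apix + c;
          if (gx < 0 || gx > n - 1 || gy < 0 || gy > n - 1) continue;
          int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy),
              z0 = (int)std::floor(gz);
          if (x0 == n - 1) x0--;
          if (y0 == n - 1) y0--;
          if (z0 == n - 1) z0--;
          const double tx = gx - x0, ty = gy - y0, tz = gz - z0;
          double acc = 0.0;
          for (int dz2 = 0; dz2 < 2; ++dz2) {
            const double wz = dz2 ? tz : 1.0 - tz;
            for (int dy2 = 0; dy2 < 2; ++dy2) {
              const double wyz = (dy2 ? ty : 1.0 - ty) * wz;
              for (int dx2 = 0; dx2 < 2; ++dx2) {
                const double wt = (dx2 ? tx : 1.0 - tx) * wyz;
                acc += wt * V[(x0 + dx2) +
                              (size_t)n * ((y0 + dy2) + (size_t)n * (z0 + dz2))];
              }
            }
          }
          const size_t idx = ix + (size_t)n * (jy + (size_t)n * kz);
          O[idx] += acc;
          counts[idx] += 1.0;
        }
      }
    }
  }
  for (size_t i = 0; i < counts.size(); ++i)
    if (counts[i] > 0) O[i] /= counts[i];
  out.attr("dim") = IntegerVector::create(n, n, n);
  return out;
}
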