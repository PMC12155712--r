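#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grid layout throughout: numeric vector with dim = c(nz, nx, ny),
// voxel (z, x, y) at index z + nz * (x + nx * y), all 0-based.

static inline double sq(double v) { return v * v; }

// Render a layered retinal phantom. Layers are Gaussian bands in depth
// centred on per-(x,y) surfaces; fills are constant slabs between two
// surfaces; deposits are reflective balls (anisotropic voxels handled in um).
// [[Rcpp::export]]
List render_phantom_cpp(int nz, double dz, double dxy,
                        List layer_depth, NumericVector layer_refl,
                        NumericVector layer_sigma, List layer_scale,
                        double background,
                        List fill_top, List fill_bot,
                        NumericVector fill_refl, List fill_scale,
                        NumericMatrix sdd) {
  NumericMatrix d0 = layer_depth[0];
  const int nx = d0.nrow(), ny = d0.ncol();
  const int nlayer = layer_depth.size();
  const int nfill = fill_top.size();
  NumericVector grid(static_cast<R_xlen_t>(nz) * nx * ny, background);

  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      double *col = &grid[static_cast<R_xlen_t>(nz) * (ix + static_cast<R_xlen_t>(nx) * iy)];
      for (int l = 0; l < nlayer; ++l) {
        NumericMatrix dep = layer_depth[l];
        NumericMatrix scl = layer_scale[l];
        double mu = dep(ix, iy), sig = layer_sigma[l];
        double amp = layer_refl[l] * scl(ix, iy);
        int z0 = std::max(0, (int)std::floor((mu - 4.0 * sig) / dz));
        int z1 = std::min(nz - 1, (int)std::ceil((mu + 4.0 * sig) / dz));
        for (int z = z0; z <= z1; ++z) {
          double zz = z * dz;
          col[z] += amp * std::exp(-sq(zz - mu) / (2.0 * sig * sig));
        }
      }
      for (int f = 0; f < nfill; ++f) {
        NumericMatrix top = fill_top[f];
        NumericMatrix bot = fill_bot[f];
        NumericMatrix scl = fill_scale[f];
        double zt = top(ix, iy), zb = bot(ix, iy);
        if (!(zb > zt)) continue;
        double amp = fill_refl[f] * scl(ix, iy);
        int z0 = std::max(0, (int)std::ceil(zt / dz));
        int z1 = std::min(nz - 1, (int)std::floor(zb / dz));
        for (int z = z0; z <= z1; ++z) col[z] += amp;
      }
    }
  }

  // deposits: ball of radius r_um centred at (cx_vox, cy_vox, cz_um)
  const int nsdd = sdd.nrow();
  IntegerVector counts(nsdd);
  for (int s = 0; s < nsdd; ++s) {
    double cx = sdd(s, 0), cy = sdd(s, 1), cz = sdd(s, 2);
    double r = sdd(s, 3), refl = sdd(s, 4);
    int x0 = std::max(0, (int)std::floor(cx - r / dxy));
    int x1 = std::min(nx - 1, (int)std::ceil(cx + r / dxy));
    int y0 = std::max(0, (int)std::floor(cy - r / dxy));
    int y1 = std::min(ny - 1, (int)std::ceil(cy + r / dxy));
    int z0 = std::max(0, (int)std::floor((cz - r) / dz));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + r) / dz));
    int n = 0;
    for (int iy = y0; iy <= y1; ++iy)
      for (int ix = x0; ix <= x1; ++ix) {
        double dt2 = sq((ix - cx) * dxy) + sq((iy - cy) * dxy);
        if (dt2 > r * r) continue;
        double *col = &grid[static_cast<R_xlen_t>(nz) * (ix + static_cast<R_xlen_t>(nx) * iy)];
        for (int z = z0; z <= z1; ++z) {
          if (dt2 + sq(z * dz - cz) <= r * r) { col[z] += refl; ++n; }
        }
      }
    counts[s] = n;
  }
  grid.attr("dim") = IntegerVector::create(nz, nx, ny);
  return List::create(_["grid"] = grid, _["sdd_voxels"] = counts);
}

// Sample full-depth columns out of a grid: bilinear in (x, y), with the
// whole column shifted axially by dzv voxels (linear interpolation in z).
// Transverse positions fully outside the grid give background and a flag.
// [[Rcpp::export]]
List sample_columns_cpp(NumericVector grid, NumericVector xv,
                        NumericVector yv, NumericVector dzv,
                        double background) {
  IntegerVector dim = grid.attr("dim");
  const int nz = dim[0], nx = dim[1], ny = dim[2];
  const int nA = xv.size();
  NumericMatrix out(nz, nA);
  LogicalVector oob(nA);
  for (int a = 0; a < nA; ++a) {
    double x = xv[a], y = yv[a], dzs = dzv[a];
    if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1) {
      oob[a] = true;
      for (int z = 0; z < nz; ++z) out(z, a) = background;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
    double fx = x - x0, fy = y - y0;
    double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
    double w01 = (1 - fx) * fy, w11 = fx * fy;
    const double *c00 = &grid[static_cast<R_xlen_t>(nz) * (x0 + static_cast<R_xlen_t>(nx) * y0)];
    const double *c10 = &grid[static_cast<R_xlen_t>(nz) * (x1 + static_cast<R_xlen_t>(nx) * y0)];
    const double *c01 = &grid[static_cast<R_xlen_t>(nz) * (x0 + static_cast<R_xlen_t>(nx) * y1)];
    const double *c11 = &grid[static_cast<R_xlen_t>(nz) * (x1 + static_cast<R_xlen_t>(nx) * y1)];
    for (int z = 0; z < nz; ++z) {
      double zs = z + dzs;
      if (zs < 0 || zs > nz - 1) { out(z, a) = background; continue; }
      int z0 = (int)std::floor(zs);
      int z1i = std::min(z0 + 1, nz - 1);
      double fz = zs - z0;
      double v0 = w00 * c00[z0] + w10 * c10[z0] + w01 * c01[z0] + w11 * c11[z0];
      double v1 = w00 * c00[z1i] + w10 * c10[z1i] + w01 * c01[z1i] + w11 * c11[z1i];
      out(z, a) = (1 - fz) * v0 + fz * v1;
    }
  }
  return List::create(_["intensity"] = out, _["oob"] = oob);
}

// Trilinear scatter of sample columns into accumulation grids (in place).
// Column a, voxel k lands at grid position (k + zs[a], xv[a], yv[a]).
// [[Rcpp::export]]
void scatter_cpp(NumericMatrix cols, NumericVector xv, NumericVector yv,
                 NumericVector zs, NumericVector sum, NumericVector wsum) {
  IntegerVector dim = sum.attr("dim");
  const int nz = dim[0], nx = dim[1], ny = dim[2];
  const int nzc = cols.nrow(), nA = cols.ncol();
  for (int a = 0; a < nA; ++a) {
    double x = xv[a], y = yv[a];
    if (!R_finite(x) || !R_finite(y)) continue;
    if (x < -1 || x > nx || y < -1 || y > ny) continue;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    double fx = x - x0, fy = y - y0;
    double wt[4] = {(1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy};
    int xi[4] = {x0, x0 + 1, x0, x0 + 1};
    int yi[4] = {y0, y0, y0 + 1, y0 + 1};
    for (int k = 0; k < nzc; ++k) {
      double v = cols(k, a);
      if (!R_finite(v)) continue;
      double zpos = k + zs[a];
      if (zpos < -1 || zpos > nz) continue;
      int z0 = (int)std::floor(zpos);
      double fz = zpos - z0;
      for (int c = 0; c < 4; ++c) {
        if (xi[c] < 0 || xi[c] >= nx || yi[c] < 0 || yi[c] >= ny) continue;
        for (int dzi = 0; dzi < 2; ++dzi) {
          int zc = z0 + dzi;
          if (zc < 0 || zc >= nz) continue;
          double w = wt[c] * (dzi == 0 ? 1 - fz : fz);
          if (w <= 0) continue;
          R_xlen_t idx = zc + static_cast<R_xlen_t>(nz) * (xi[c] + static_cast<R_xlen_t>(nx) * yi[c]);
          sum[idx] += w * v;
          wsum[idx] += w;
        }
      }
    }
  }
}

// Trilinear gather of sample columns from a value grid that uses NaN for
// holes; any invalid corner invalidates the sample (NaN output).
// [[Rcpp::export]]
NumericMatrix gather_cpp(NumericVector grid, int nzc, NumericVector xv,
                         NumericVector yv, NumericVector zs) {
  IntegerVector dim = grid.attr("dim");
  const int nz = dim[0], nx = dim[1], ny = dim[2];
  const int nA = xv.size();
  NumericMatrix out(nzc, nA);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int a = 0; a < nA; ++a) {
    double x = xv[a], y = yv[a];
    if (!R_finite(x) || !R_finite(y)) continue;
    if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1) continue;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
    double fx = x - x0, fy = y - y0;
    double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
    double w01 = (1 - fx) * fy, w11 = fx * fy;
    const double *c00 = &grid[static_cast<R_xlen_t>(nz) * (x0 + static_cast<R_xlen_t>(nx) * y0)];
    const double *c10 = &grid[static_cast<R_xlen_t>(nz) * (x1 + static_cast<R_xlen_t>(nx) * y0)];
    const double *c01 = &grid[static_cast<R_xlen_t>(nz) * (x0 + static_cast<R_xlen_t>(nx) * y1)];
    const double *c11 = &grid[static_cast<R_xlen_t>(nz) * (x1 + static_cast<R_xlen_t>(nx) * y1)];
    for (int k = 0; k < nzc; ++k) {
      double zpos = k + zs[a];
      if (zpos < 0 || zpos > nz - 1) continue;
      int z0 = (int)std::floor(zpos);
      int z1i = std::min(z0 + 1, nz - 1);
      double fz = zpos - z0;
      double a00 = c00[z0], a10 = c10[z0], a01 = c01[z0], a11 = c11[z0];
      double b00 = c00[z1i], b10 = c10[z1i], b01 = c01[z1i], b11 = c11[z1i];
      if (!R_finite(a00) || !R_finite(a10) || !R_finite(a01) || !R_finite(a11) ||
          !R_finite(b00) || !R_finite(b10) || !R_finite(b01) || !R_finite(b11))
        continue;
      double v0 = w00 * a00 + w10 * a10 + w01 * a01 + w11 * a11;
      double v1 = w00 * b00 + w10 * b10 + w01 * b01 + w11 * b11;
      out(k, a) = (1 - fz) * v0 + fz * v1;
    }
  }
  return out;
}

// SSD of one B-scan against a reference grid over a lattice of candidate
// offsets. Sample position for column a, row k, candidate (ox, oy, oz):
// (k + zoff + oz, xs[a] + ox, ys[a] + oy). NaNs (holes) are skipped; the
// per-candidate count of valid voxels is returned alongside.
// [[Rcpp::export]]
List ssd_search_cpp(NumericMatrix bscan, NumericVector xs, NumericVector ys,
                    double zoff, NumericVector ref,
                    NumericVector ox, NumericVector oy, NumericVector oz) {
  IntegerVector dim = ref.attr("dim");
  const int nz = dim[0], nx = dim[1], ny = dim[2];
  const int nzc = bscan.nrow(), nA = bscan.ncol();
  const int n1 = ox.size(), n2 = oy.size(), n3 = oz.size();
  NumericVector ssd(n1 * n2 * n3);
  IntegerVector cnt(n1 * n2 * n3);
  std::vector<double> tmp(nz);
  // loop order keeps the transverse interpolation (tmp column) shared
  // across all axial candidates of one (A-scan, ox, oy) combination
  for (int i2 = 0; i2 < n2; ++i2) {
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int a = 0; a < nA; ++a) {
        double x = xs[a] + ox[i1], y = ys[a] + oy[i2];
        if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1) continue;
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
        double fx = x - x0, fy = y - y0;
        double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
        double w01 = (1 - fx) * fy, w11 = fx * fy;
        const double *c00 = &ref[static_cast<R_xlen_t>(nz) * (x0 + static_cast<R_xlen_t>(nx) * y0)];
        const double *c10 = &ref[static_cast<R_xlen_t>(nz) * (x1 + static_cast<R_xlen_t>(nx) * y0)];
        const double *c01 = &ref[static_cast<R_xlen_t>(nz) * (x0 + static_cast<R_xlen_t>(nx) * y1)];
        const double *c11 = &ref[static_cast<R_xlen_t>(nz) * (x1 + static_cast<R_xlen_t>(nx) * y1)];
        for (int z = 0; z < nz; ++z)
          tmp[z] = w00 * c00[z] + w10 * c10[z] + w01 * c01[z] + w11 * c11[z];
        const double *bcol = &bscan(0, a);
        for (int i3 = 0; i3 < n3; ++i3) {
          double zbase = zoff + oz[i3];
          double acc = 0; int n = 0;
          int k0 = std::max(0, (int)std::ceil(-zbase));
          int k1 = std::min(nzc - 1, (int)std::floor(nz - 1 - zbase));
          for (int k = k0; k <= k1; ++k) {
            double v = bcol[k];
            if (!R_finite(v)) continue;
            double zpos = k + zbase;
            int z0 = (int)zpos;
            int z1i = std::min(z0 + 1, nz - 1);
            double fz = zpos - z0;
            double r = (1 - fz) * tmp[z0] + fz * tmp[z1i];
            if (!R_finite(r)) continue;
            acc += sq(v - r);
            ++n;
          }
          int idx = i1 + n1 * (i2 + n2 * i3);
          ssd[idx] += acc;
          cnt[idx] += n;
        }
      }
    }
  }
  ssd.attr("dim") = IntegerVector::create(n1, n2, n3);
  cnt.attr("dim") = IntegerVector::create(n1, n2, n3);
  return List::create(_["ssd"] = ssd, _["n"] = cnt);
}

// Minimum-cost continuous path through a (nz x nA) cost image: one depth
// per column, adjacent columns differ by at most max_step rows.
// [[Rcpp::export]]
IntegerVector dp_surface_cpp(NumericMatrix cost, int max_step) {
  const int nz = cost.nrow(), nA = cost.ncol();
  NumericMatrix acc(nz, nA);
  IntegerMatrix from(nz, nA);
  for (int z = 0; z < nz; ++z) acc(z, 0) = cost(z, 0);
  for (int a = 1; a < nA; ++a) {
    for (int z = 0; z < nz; ++z) {
      double best = R_PosInf; int bz = z;
      int z0 = std::max(0, z - max_step), z1 = std::min(nz - 1, z + max_step);
      for (int p = z0; p <= z1; ++p) {
        if (acc(p, a - 1) < best) { best = acc(p, a - 1); bz = p; }
      }
      acc(z, a) = cost(z, a) + best;
      from(z, a) = bz;
    }
  }
  IntegerVector path(nA);
  double best = R_PosInf; int bz = 0;
  for (int z = 0; z < nz; ++z)
    if (acc(z, nA - 1) < best) { best = acc(z, nA - 1); bz = z; }
  path[nA - 1] = bz;
  for (int a = nA - 1; a > 0; --a) path[a - 1] = from(path[a], a);
  return path;
}

// Bilinear rotation of a 2D image about (cx, cy) by theta radians.
// [[Rcpp::export]]
NumericMatrix rotate2d_cpp(NumericMatrix img, double theta, double cx,
                           double cy, double bg) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double ct = std::cos(theta), st = std::sin(theta);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      // inverse map: source = R(-theta) * (p - c) + c
      double dx = i - cx, dy = j - cy;
      double sx = ct * dx + st * dy + cx;
      double sy = -st * dx + ct * dy + cy;
      if (sx < 0 || sx > nr - 1 || sy < 0 || sy > nc - 1) { out(i, j) = bg; continue; }
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      int x1 = std::min(x0 + 1, nr - 1), y1 = std::min(y0 + 1, nc - 1);
      double fx = sx - x0, fy = sy - y0;
      out(i, j) = (1 - fx) * (1 - fy) * img(x0, y0) + fx * (1 - fy) * img(x1, y0) +
                  (1 - fx) * fy * img(x0, y1) + fx * fy * img(x1, y1);
    }
  }
  return out;
}
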