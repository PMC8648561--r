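#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Parallel-beam Radon transform of one axial slice.
// slice: nx x ny matrix (x fastest). Rays at angle theta have direction
// v = (-sin t, cos t); lateral offset u = (cos t, sin t) relative to the
// rotation centre (cx, cy) given in 1-based voxel coordinates.
// tvals are lateral ray positions in voxel units. Returns n_angles x n_t
// line integrals in voxel-length units (caller multiplies by voxel size).
// [[Rcpp::export]]
NumericMatrix radon_cpp(NumericMatrix slice, NumericVector angles_rad,
                        NumericVector tvals, double cx, double cy,
                        double step) {
  const int nx = slice.nrow(), ny = slice.ncol();
  const int na = angles_rad.size(), nt = tvals.size();
  NumericMatrix out(na, nt);
  const double smax = 0.75 * std::sqrt((double)nx * nx + (double)ny * ny);
  const int ns = (int)std::ceil(2.0 * smax / step);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int it = 0; it < nt; ++it) {
      const double t = tvals[it];
      double acc = 0.0;
      // base point of the ray
      const double bx = cx + t * ct, by = cy + t * st;
      for (int is = 0; is <= ns; ++is) {
        const double s = -smax + is * step;
        const double x = bx - s * st;  // v = (-sin, cos)
        const double y = by + s * ct;
        const int ix = (int)std::floor(x), iy = (int)std::floor(y);
        if (ix < 1 || ix >= nx || iy < 1 || iy >= ny) continue;
        const double fx = x - ix, fy = y - iy;
        // bilinear; 1-based voxel centres at integer coordinates
        const double v00 = slice(ix - 1, iy - 1), v10 = slice(ix, iy - 1);
        const double v01 = slice(ix - 1, iy), v11 = slice(ix, iy);
        acc += (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
               (1 - fx) * fy * v01 + fx * fy * v11;
      }
      out(a, it) = acc * step;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Filtered back-projection accumulator. filt: n_angles x n_cols filtered
// sinogram; cor_col is the 1-based column of the rotation centre;
// (cx, cy) the rotation centre in 1-based voxel coordinates of the
// nx x ny output grid; px_per_voxel converts voxel offsets to columns.
// Caller multiplies by delta_theta.
// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix filt, NumericVector angles_rad,
                              double cor_col, int nx, int ny,
                              double cx, double cy, double px_per_voxel) {
  const int na = angles_rad.size(), nc = filt.ncol();
  NumericMatrix out(nx, ny);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int iy = 0; iy < ny; ++iy) {
      const double dy = (iy + 1 - cy) * st;
      for (int ix = 0; ix < nx; ++ix) {
        const double t = ((ix + 1 - cx) * ct + dy) * px_per_voxel;
        const double col = cor_col + t;
        const int c0 = (int)std::floor(col);
        if (c0 < 1 || c0 >= nc) continue;
        const double f = col - c0;
        out(ix, iy) += (1 - f) * filt(a, c0 - 1) + f * filt(a, c0);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance of foreground voxels to the nearest background voxel, in voxel
// units squared. mask: logical, dims d (nx, ny, nz).
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 1e30 : 0.0;
  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Weighted chamfer distance transform, two-pass, weights (face, edge,
// vertex, knight) applied to the 26-neighbourhood plus the 24 (1,1,2)-type
// displacements. Integer-weight distances; caller normalises by w_face.
// [[Rcpp::export]]
NumericVector chamfer_cpp(LogicalVector mask, IntegerVector dims,
                          double wf, double we, double wv, double wk) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;

  // build full displacement/weight table (prime displacements)
  struct Off { int x, y, z; double w; };
  std::vector<Off> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        double w = (m == 1) ? wf : (m == 2) ? we : wv;
        offs.push_back({dx, dy, dz, w});
      }
  for (int dz = -2; dz <= 2; ++dz)
    for (int dy = -2; dy <= 2; ++dy)
      for (int dx = -2; dx <= 2; ++dx) {
        int ax = std::abs(dx), ay = std::abs(dy), az = std::abs(dz);
        int s[3] = {ax, ay, az};
        std::sort(s, s + 3);
        if (s[0] == 1 && s[1] == 1 && s[2] == 2)
          offs.push_back({dx, dy, dz, wk});
      }

  auto lex_forward = [](const Off& o) {
    if (o.z != 0) return o.z < 0;
    if (o.y != 0) return o.y < 0;
    return o.x < 0;
  };
  std::vector<Off> fwd, bwd;
  for (auto& o : offs) (lex_forward(o) ? fwd : bwd).push_back(o);

  auto sweep = [&](const std::vector<Off>& half, bool forward) {
    int z0 = forward ? 0 : nz - 1, z1 = forward ? nz : -1, zs = forward ? 1 : -1;
    int y0 = forward ? 0 : ny - 1, y1 = forward ? ny : -1, ys = forward ? 1 : -1;
    int x0 = forward ? 0 : nx - 1, x1 = forward ? nx : -1, xs = forward ? 1 : -1;
    for (int z = z0; z != z1; z += zs)
      for (int y = y0; y != y1; y += ys)
        for (int x = x0; x != x1; x += xs) {
          R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
          if (d[i] == 0.0) continue;
          double best = d[i];
          for (auto& o : half) {
            int px = x + o.x, py = y + o.y, pz = z + o.z;
            if (px < 0 || px >= nx || py < 0 || py >= ny ||
                pz < 0 || pz >= nz) continue;
            double cand = d[(R_xlen_t)pz * nx * ny + (R_xlen_t)py * nx + px] + o.w;
            if (cand < best) best = cand;
          }
          d[i] = best;
        }
  };
  sweep(fwd, true);
  sweep(bwd, false);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = d[i];
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness (largest inscribed sphere) by sphere painting from a
// Euclidean distance map (voxel units). Voxels are visited in order of
// decreasing inscribed-sphere radius; each paints 2*r onto every voxel of
// its ball that does not already carry a larger value.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dims,
                                  NumericVector dist) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n);
  std::vector<R_xlen_t> idx;
  idx.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) idx.push_back(i);
  std::sort(idx.begin(), idx.end(),
            [&](R_xlen_t a, R_xlen_t b) { return dist[a] > dist[b]; });
  for (R_xlen_t k = 0; k < (R_xlen_t)idx.size(); ++k) {
    const R_xlen_t i = idx[k];
    const double r = dist[i];
    const double val = 2.0 * r;
    if (th[i] >= val) continue;  // already inside a larger sphere
    const int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
    const int ri = (int)std::floor(r);
    const double r2 = r * r;
    for (int dz = -ri; dz <= ri; ++dz) {
      const int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        const int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        const double rem = r2 - (double)dz * dz - (double)dy * dy;
        if (rem < 0) continue;
        const int rx = (int)std::floor(std::sqrt(rem));
        const R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
        for (int dx = -rx; dx <= rx; ++dx) {
          const int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          if (th[base + xx] < val) th[base + xx] = val;
        }
      }
    }
  }
  return th;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6- or 26-connectivity), BFS with an
// explicit stack. Returns integer labels, 0 for background.
// [[Rcpp::export]]
IntegerVector label_cpp(LogicalVector mask, IntegerVector dims,
                        int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      const int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
      for (auto& o : offs) {
        const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}
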