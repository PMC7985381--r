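#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Parallel-beam projection of one square slice by mass-conserving bilinear
// splat: every voxel deposits its value into the two detector bins adjacent
// to t = x*cos(theta) + y*sin(theta) + cor, so sum(projection) == sum(slice)
// exactly for every angle. Angles counterclockwise, angle 0 aligns detector
// columns with the slice x axis (matrix columns).
// [[Rcpp::export]]
NumericMatrix cpp_project_slice(NumericMatrix slice, NumericVector angles_rad,
                                double cor_offset) {
  const int ny = slice.nrow(), nx = slice.ncol();
  const int na = angles_rad.size(), W = nx;
  const double cy = (ny - 1) / 2.0, cx = (nx - 1) / 2.0;
  const double cdet = (W - 1) / 2.0;
  NumericMatrix out(na, W);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int ix = 0; ix < nx; ++ix) {
      const double x = ix - cx;
      for (int iy = 0; iy < ny; ++iy) {
        const double v = slice(iy, ix);
        if (v == 0.0) continue;
        const double y = iy - cy;
        const double t = x * ct + y * st + cor_offset + cdet;
        const int i0 = (int)std::floor(t);
        const double w = t - i0;
        if (i0 >= 0 && i0 < W) out(a, i0) += v * (1.0 - w);
        if (i0 + 1 >= 0 && i0 + 1 < W) out(a, i0 + 1) += v * w;
      }
    }
  }
  return out;
}

// Back-project one filtered sinogram (n_angles x W) onto a W x W slice with
// linear interpolation along the detector; voxels outside the inscribed
// field-of-view circle are set to 0. Accumulation weight pi / n_angles.
// [[Rcpp::export]]
NumericMatrix cpp_backproject_slice(NumericMatrix fsino, NumericVector angles_rad,
                                    double cor_offset) {
  const int na = fsino.nrow(), W = fsino.ncol();
  const double c = (W - 1) / 2.0;
  const double r2 = (W / 2.0) * (W / 2.0);
  const double wgt = M_PI / na;
  NumericMatrix out(W, W);
  std::vector<double> cts(na), sts(na);
  for (int a = 0; a < na; ++a) {
    cts[a] = std::cos(angles_rad[a]);
    sts[a] = std::sin(angles_rad[a]);
  }
  for (int ix = 0; ix < W; ++ix) {
    const double x = ix - c;
    for (int iy = 0; iy < W; ++iy) {
      const double y = iy - c;
      if (x * x + y * y > r2) continue;
      double acc = 0.0;
      for (int a = 0; a < na; ++a) {
        const double t = x * cts[a] + y * sts[a] + cor_offset + c;
        const int i0 = (int)std::floor(t);
        if (i0 < 0 || i0 + 1 >= W) continue;
        const double w = t - i0;
        acc += (1.0 - w) * fsino(a, i0) + w * fsino(a, i0 + 1);
      }
      out(iy, ix) = acc * wgt;
    }
  }
  return out;
}

static inline int lin_idx(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 3D connected-component labeling (BFS) for connectivity 6 / 18 / 26.
// Components are numbered 1..n in order of first voxel encountered in the
// array's linear (z-fastest) scan, which is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.push_back({dz, dy, dx});
      }
  IntegerVector labels(mask.size(), 0);
  int cur = 0;
  std::queue<std::array<int, 3>> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const int i = lin_idx(z, y, x, nz, ny);
        if (!mask[i] || labels[i] != 0) continue;
        ++cur;
        labels[i] = cur;
        q.push({z, y, x});
        while (!q.empty()) {
          std::array<int, 3> p = q.front();
          q.pop();
          for (size_t k = 0; k < nb.size(); ++k) {
            const int z2 = p[0] + nb[k][0], y2 = p[1] + nb[k][1], x2 = p[2] + nb[k][2];
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
            const int j = lin_idx(z2, y2, x2, nz, ny);
            if (mask[j] && labels[j] == 0) {
              labels[j] = cur;
              q.push({z2, y2, x2});
            }
          }
        }
      }
  labels.attr("n_labels") = cur;
  return labels;
}

// Binary dilation (dilate = true) or erosion with an arbitrary offset set
// (rows of `offsets` are dz, dy, dx). Voxels outside the array are treated
// as background.
// [[Rcpp::export]]
LogicalVector cpp_morph3d(LogicalVector mask, IntegerVector dims,
                          IntegerMatrix offsets, bool dilate) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int no = offsets.nrow();
  LogicalVector out(mask.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool acc = dilate ? false : true;
        for (int k = 0; k < no; ++k) {
          const int z2 = z + offsets(k, 0), y2 = y + offsets(k, 1), x2 = x + offsets(k, 2);
          bool v = false;
          if (z2 >= 0 && z2 < nz && y2 >= 0 && y2 < ny && x2 >= 0 && x2 < nx)
            v = mask[lin_idx(z2, y2, x2, nz, ny)];
          if (dilate) {
            if (v) { acc = true; break; }
          } else {
            if (!v) { acc = false; break; }
          }
        }
        out[lin_idx(z, y, x, nz, ny)] = acc;
      }
  return out;
}

// Rasterize ellipsoidal cells into a (nz, ny, nx) volume. A voxel belongs to
// a cell when its center lies inside the ellipsoid. centers/semiaxes are in
// voxel units (z, y, x order); `rot` holds row-concatenated 3x3 body->world
// rotation matrices (one row of 9 per cell, row-major).
// [[Rcpp::export]]
NumericVector cpp_render_cells(IntegerVector dims, NumericMatrix centers,
                               NumericMatrix semiaxes, NumericMatrix rot,
                               NumericVector values) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector vol(nz * ny * nx, 0.0);
  const int n = centers.nrow();
  for (int i = 0; i < n; ++i) {
    const double cz = centers(i, 0), cy = centers(i, 1), cx = centers(i, 2);
    const double a = semiaxes(i, 0), b = semiaxes(i, 1), cc = semiaxes(i, 2);
    const double rmax = std::max(a, std::max(b, cc));
    double R[9];
    for (int k = 0; k < 9; ++k) R[k] = rot(i, k);
    const int z0 = std::max(0, (int)std::floor(cz - rmax)), z1 = std::min(nz - 1, (int)std::ceil(cz + rmax));
    const int y0 = std::max(0, (int)std::floor(cy - rmax)), y1 = std::min(ny - 1, (int)std::ceil(cy + rmax));
    const int x0 = std::max(0, (int)std::floor(cx - rmax)), x1 = std::min(nx - 1, (int)std::ceil(cx + rmax));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          const double dz = z - cz, dy = y - cy, dx = x - cx;
          // body coords u = R^T d  (R row-major: R[3*r+c] = R_{rc})
          const double u0 = R[0] * dz + R[3] * dy + R[6] * dx;
          const double u1 = R[1] * dz + R[4] * dy + R[7] * dx;
          const double u2 = R[2] * dz + R[5] * dy + R[8] * dx;
          const double q = (u0 * u0) / (a * a) + (u1 * u1) / (b * b) + (u2 * u2) / (cc * cc);
          if (q <= 1.0) vol[lin_idx(z, y, x, nz, ny)] = values[i];
        }
  }
  vol.attr("dim") = dims;
  return vol;
}
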