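// Volume sampling, resampling and perspective ray-casting primitives.
// World convention: 0-based voxel indices, world coordinate of a voxel
// centre = index * voxel_size (mm).  All marching is done in world mm.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z, double fill) {
  // x,y,z in voxel units
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const int sx = 1, sy = nx, sz = nx * ny;
  const double* p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts_vox, double fill) {
  int n = pts_vox.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (int i = 0; i < n; i++)
    out[i] = tri_sample(v, dim[0], dim[1], dim[2],
                        pts_vox(i, 0), pts_vox(i, 1), pts_vox(i, 2), fill);
  return out;
}

// Output voxel index (ox,oy,oz) maps to input voxel coords A %*% o + t.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim,
                                  NumericMatrix A, NumericVector t,
                                  IntegerVector odim, double fill) {
  int nx = odim[0], ny = odim[1], nz = odim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = odim;
  const double* v = REAL(vol);
  double* o = REAL(out);
  R_xlen_t idx = 0;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++, idx++) {
        double ix = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + t[0];
        double iy = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + t[1];
        double iz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + t[2];
        o[idx] = tri_sample(v, dim[0], dim[1], dim[2], ix, iy, iz, fill);
      }
  return out;
}

// Separable Gaussian smoothing, sigma in voxel units, truncated at 3 sigma.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; i++) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& w : k) w /= s;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(REAL(vol), REAL(vol) + n), b(n);
  const int stride[3] = {1, nx, nx * ny};
  const int len[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ax++) {
    int st = stride[ax], L = len[ax];
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          int pos[3] = {x, y, z};
          R_xlen_t idx = (R_xlen_t)x + (R_xlen_t)y * nx + (R_xlen_t)z * nx * ny;
          double acc = 0;
          for (int i = -r; i <= r; i++) {
            int p = pos[ax] + i;
            if (p < 0) p = 0;
            if (p >= L) p = L - 1;
            acc += k[i + r] * a[idx + (R_xlen_t)(p - pos[ax]) * st];
          }
          b[idx] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Perspective ray casting with front-to-back alpha compositing.
// Opacity ramps linearly from 0 at wl-ww/2 to 1 at wl+ww/2; emission equals
// opacity (grayscale).  Records the first world point where accumulated
// opacity crosses 0.5.  Image row 1 = top of frame.
// [[Rcpp::export]]
List cpp_raycast(NumericVector vol, IntegerVector dim, NumericVector vox,
                 NumericVector cam, NumericVector look, NumericVector up,
                 double tanfov, int npix, double wl, double ww, double step,
                 double fill) {
  const double* v = REAL(vol);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double d0[3] = {look[0] - cam[0], look[1] - cam[1], look[2] - cam[2]};
  double nd = std::sqrt(d0[0] * d0[0] + d0[1] * d0[1] + d0[2] * d0[2]);
  for (int i = 0; i < 3; i++) d0[i] /= nd;
  // right = d0 x up ; up_img = right x d0
  double rt[3] = {d0[1] * up[2] - d0[2] * up[1],
                  d0[2] * up[0] - d0[0] * up[2],
                  d0[0] * up[1] - d0[1] * up[0]};
  double nr = std::sqrt(rt[0] * rt[0] + rt[1] * rt[1] + rt[2] * rt[2]);
  if (nr < 1e-9) stop("camera direction parallel to up vector");
  for (int i = 0; i < 3; i++) rt[i] /= nr;
  double ui[3] = {rt[1] * d0[2] - rt[2] * d0[1],
                  rt[2] * d0[0] - rt[0] * d0[2],
                  rt[0] * d0[1] - rt[1] * d0[0]};
  double lo = wl - ww / 2.0;
  NumericMatrix img(npix, npix);
  NumericMatrix hit(npix * npix, 3);
  std::fill(hit.begin(), hit.end(), NA_REAL);
  // world bounding box of voxel centres
  double bmax[3] = {(nx - 1) * vox[0], (ny - 1) * vox[1], (nz - 1) * vox[2]};
  double tmax_global = nd + std::sqrt(bmax[0] * bmax[0] + bmax[1] * bmax[1] +
                                      bmax[2] * bmax[2]);
  for (int i = 0; i < npix; i++) {       // rows, top to bottom
    double py = 1.0 - 2.0 * (i + 0.5) / npix;
    for (int j = 0; j < npix; j++) {     // cols, left to right
      double px = 2.0 * (j + 0.5) / npix - 1.0;
      double dir[3];
      double nn = 0;
      for (int a = 0; a < 3; a++) {
        dir[a] = d0[a] + tanfov * (px * rt[a] + py * ui[a]);
        nn += dir[a] * dir[a];
      }
      nn = std::sqrt(nn);
      for (int a = 0; a < 3; a++) dir[a] /= nn;
      // clip ray to bbox
      double t0 = 0, t1 = tmax_global;
      bool miss = false;
      for (int a = 0; a < 3; a++) {
        if (std::fabs(dir[a]) < 1e-12) {
          if (cam[a] < 0 || cam[a] > bmax[a]) { miss = true; break; }
        } else {
          double ta = (0 - cam[a]) / dir[a], tb = (bmax[a] - cam[a]) / dir[a];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
        }
      }
      if (miss || t1 <= t0) continue;
      double T = 1.0, C = 0.0;
      bool hitdone = false;
      for (double t = t0; t <= t1; t += step) {
        double wx = cam[0] + t * dir[0], wy = cam[1] + t * dir[1],
               wz = cam[2] + t * dir[2];
        double val = tri_sample(v, nx, ny, nz, wx / vox[0], wy / vox[1],
                                wz / vox[2], fill);
        double a = (val - lo) / ww;
        if (a <= 0) continue;
        if (a > 1) a = 1;
        C += T * a * a;
        T *= (1.0 - a);
        if (!hitdone && (1.0 - T) >= 0.5) {
          int pid = i + j * npix;  // column-major (row i, col j)
          hit(pid, 0) = wx; hit(pid, 1) = wy; hit(pid, 2) = wz;
          hitdone = true;
        }
        if (T < 1e-3) break;
      }
      img(i, j) = C > 1 ? 1.0 : C;
    }
  }
  return List::create(_["image"] = img, _["hits"] = hit);
}

// Nearest face centroid lookup via a uniform spatial hash.
// Returns 1-based face indices, NA when nothing within max_dist.
// [[Rcpp::export]]
IntegerVector cpp_nearest_face(NumericMatrix pts, NumericMatrix cent,
                               double cell, double max_dist) {
  int np = pts.nrow(), nc = cent.nrow();
  std::unordered_map<int64_t, std::vector<int>> grid;
  auto key = [&](int ix, int iy, int iz) {
    return ((int64_t)(ix + 1048576) << 42) | ((int64_t)(iy + 1048576) << 21) |
           (int64_t)(iz + 1048576);
  };
  for (int c = 0; c < nc; c++) {
    int ix = (int)std::floor(cent(c, 0) / cell),
        iy = (int)std::floor(cent(c, 1) / cell),
        iz = (int)std::floor(cent(c, 2) / cell);
    grid[key(ix, iy, iz)].push_back(c);
  }
  int rmax = (int)std::ceil(max_dist / cell);
  IntegerVector out(np, NA_INTEGER);
  for (int p = 0; p < np; p++) {
    if (NumericVector::is_na(pts(p, 0))) continue;
    int ix = (int)std::floor(pts(p, 0) / cell),
        iy = (int)std::floor(pts(p, 1) / cell),
        iz = (int)std::floor(pts(p, 2) / cell);
    double best = max_dist * max_dist;
    int bi = NA_INTEGER, found_r = -1;
    for (int r = 0; r <= rmax; r++) {
      // one extra shell after the first hit guarantees the true nearest
      if (found_r >= 0 && r > found_r + 1) break;
      for (int dx = -r; dx <= r; dx++)
        for (int dy = -r; dy <= r; dy++)
          for (int dz = -r; dz <= r; dz++) {
            if (std::max({std::abs(dx), std::abs(dy), std::abs(dz)}) != r)
              continue;
            auto it = grid.find(key(ix + dx, iy + dy, iz + dz));
            if (it == grid.end()) continue;
            for (int c : it->second) {
              double d2 = 0;
              for (int a = 0; a < 3; a++) {
                double d = cent(c, a) - pts(p, a);
                d2 += d * d;
              }
              if (d2 < best) {
                best = d2;
                bi = c + 1;
                if (found_r < 0) found_r = r;
              }
            }
          }
    }
    out[p] = bi;
  }
  return out;
}

// March outward from world-space origins along unit directions, find where the
// (smoothed) field drops below `level`; linear interpolation between samples.
// Returns the world radius in mm (NA when the origin is already below level or
// no crossing is found within rmax).
// [[Rcpp::export]]
NumericVector cpp_ray_isocrossing(NumericVector vol, IntegerVector dim,
                                  NumericVector vox, NumericMatrix origins,
                                  NumericMatrix dirs, double level,
                                  double rmax, double step) {
  int n = origins.nrow();
  const double* v = REAL(vol);
  NumericVector out(n, NA_REAL);
  for (int i = 0; i < n; i++) {
    double prev = tri_sample(v, dim[0], dim[1], dim[2],
                             origins(i, 0) / vox[0], origins(i, 1) / vox[1],
                             origins(i, 2) / vox[2], 0.0);
    if (prev < level) continue;
    double tprev = 0;
    for (double t = step; t <= rmax; t += step) {
      double val = tri_sample(
          v, dim[0], dim[1], dim[2], (origins(i, 0) + t * dirs(i, 0)) / vox[0],
          (origins(i, 1) + t * dirs(i, 1)) / vox[1],
          (origins(i, 2) + t * dirs(i, 2)) / vox[2], 0.0);
      if (val < level) {
        out[i] = tprev + (prev - level) / (prev - val) * (t - tprev);
        break;
      }
      prev = val;
      tprev = t;
    }
  }
  return out;
}

// 6-connected component labelling of a binary mask; returns integer labels
// (0 = background), ordered by decreasing component size.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  const int* m = LOGICAL(mask);
  int next = 0;
  std::vector<R_xlen_t> stack;
  std::vector<R_xlen_t> sizes_idx;
  std::vector<R_xlen_t> sizes;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!m[s] || lab[s]) continue;
    next++;
    R_xlen_t sz = 0;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      sz++;
      int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
      const int dx[6] = {1, -1, 0, 0, 0, 0}, dy[6] = {0, 0, 1, -1, 0, 0},
                dz[6] = {0, 0, 0, 0, 1, -1};
      for (int k = 0; k < 6; k++) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * nx * ny;
        if (m[q] && !lab[q]) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
    sizes.push_back(sz);
  }
  // relabel by decreasing size
  std::vector<int> order(next);
  for (int i = 0; i < next; i++) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int rank = 0; rank < next; rank++) remap[order[rank] + 1] = rank + 1;
  for (R_xlen_t s = 0; s < n; s++)
    if (lab[s]) lab[s] = remap[lab[s]];
  return lab;
}
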