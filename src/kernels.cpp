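#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voxel kernels shared by the volume operators. All arrays are passed as
// flat vectors in R's column-major layout with dims (nx, ny, nz); indices
// here are 0-based.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// 1D squared distance transform (Felzenszwalb & Huttenlocher), helper for the
// separable exact 3D Euclidean distance transform.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= zb[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector fg, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  NumericVector out(n);
  // large finite stand-in for "no foreground" keeps the lower-envelope
  // intersection arithmetic finite (an infinite f makes s = -inf and walks
  // the envelope index out of bounds)
  const double BIG = 1e18;
  for (int i = 0; i < n; ++i) out[i] = fg[i] ? 0.0 : BIG;
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) f[x] = out[idx3(x, y, z, nx, ny)];
        dt1d(f, d, nx);
        for (int x = 0; x < nx; ++x) out[idx3(x, y, z, nx, ny)] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) f[y] = out[idx3(x, y, z, nx, ny)];
        dt1d(f, d, ny);
        for (int y = 0; y < ny; ++y) out[idx3(x, y, z, nx, ny)] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z) f[z] = out[idx3(x, y, z, nx, ny)];
        dt1d(f, d, nz);
        for (int z = 0; z < nz; ++z) out[idx3(x, y, z, nx, ny)] = d[z];
      }
  }
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// neighbourhood offset tables
static int n_offsets(int conn, int off[][3]) {
  int k = 0;
  if (conn == 6) {
    int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int i = 0; i < 6; ++i) { off[k][0]=face[i][0]; off[k][1]=face[i][1]; off[k][2]=face[i][2]; ++k; }
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          off[k][0] = dx; off[k][1] = dy; off[k][2] = dz; ++k;
        }
  }
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dims,
                           int iterations, int conn) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  NumericVector cur = clone(vol);
  int off[26][3];
  int nk = n_offsets(conn, off);
  std::vector<double> buf(nk + 1);
  for (int it = 0; it < iterations; ++it) {
    NumericVector nxt(n);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int m = 0;
          buf[m++] = cur[idx3(x, y, z, nx, ny)];
          for (int k = 0; k < nk; ++k) {
            // edge replication via clamping
            int xx = std::min(std::max(x + off[k][0], 0), nx - 1);
            int yy = std::min(std::max(y + off[k][1], 0), ny - 1);
            int zz = std::min(std::max(z + off[k][2], 0), nz - 1);
            buf[m++] = cur[idx3(xx, yy, zz, nx, ny)];
          }
          std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
          double med = buf[m / 2];
          if (m % 2 == 0) {
            std::nth_element(buf.begin(), buf.begin() + m / 2 - 1,
                             buf.begin() + m / 2);
            med = 0.5 * (med + buf[m / 2 - 1]);
          }
          nxt[idx3(x, y, z, nx, ny)] = med;
        }
    cur = nxt;
  }
  return cur;
}

// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dims,
                              IntegerMatrix seeds, double lo, double hi,
                              int conn) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  LogicalVector out(n, false);
  int off[26][3];
  int nk = n_offsets(conn, off);
  std::queue<int> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = idx3(seeds(s, 0), seeds(s, 1), seeds(s, 2), nx, ny);
    if (!out[i] && vol[i] >= lo && vol[i] <= hi) { out[i] = true; q.push(i); }
  }
  while (!q.empty()) {
    int i = q.front(); q.pop();
    int z = i / (nx * ny), rem = i % (nx * ny);
    int y = rem / nx, x = rem % nx;
    for (int k = 0; k < nk; ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int j = idx3(xx, yy, zz, nx, ny);
      if (!out[j] && vol[j] >= lo && vol[j] <= hi) { out[j] = true; q.push(j); }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int conn) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int off[26][3];
  int nk = n_offsets(conn, off);
  int cur = 0;
  std::queue<int> q;
  for (int i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0]) continue;
    lab[i0] = ++cur;
    q.push(i0);
    while (!q.empty()) {
      int i = q.front(); q.pop();
      int z = i / (nx * ny), rem = i % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int k = 0; k < nk; ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int j = idx3(xx, yy, zz, nx, ny);
        if (mask[j] && !lab[j]) { lab[j] = cur; q.push(j); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// topological thinning: sequential removal of simple points, smallest
// distance-transform value first, endpoints preserved.

// count 26-connected components of fg within the 26-neighbourhood of a voxel
static int cc26_neigh(const bool nb[27]) {
  // nb indexed dx+1 + 3*(dy+1) + 9*(dz+1); centre (index 13) excluded
  int comp[27]; for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || comp[i] >= 0) continue;
    // BFS within the 26 cells
    std::queue<int> q; comp[i] = ncomp; q.push(i);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || !nb[j] || comp[j] >= 0) continue;
        int jx = j % 3, jy = (j / 3) % 3, jz = j / 9;
        if (std::abs(jx - cx) <= 1 && std::abs(jy - cy) <= 1 &&
            std::abs(jz - cz) <= 1) { comp[j] = ncomp; q.push(j); }
      }
    }
    ++ncomp;
  }
  return ncomp;
}

// count 6-connected components of bg within the 18-neighbourhood that touch a
// face neighbour of the centre
static int cc6_bg_neigh(const bool nb[27]) {
  // 18-neighbourhood: cells with |dx|+|dy|+|dz| <= 2 excluding centre
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int ix = i % 3 - 1, iy = (i / 3) % 3 - 1, iz = i / 9 - 1;
    int m = std::abs(ix) + std::abs(iy) + std::abs(iz);
    in18[i] = (i != 13) && m <= 2;
  }
  int comp[27]; for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || comp[i] >= 0) continue;
    int ix = i % 3 - 1, iy = (i / 3) % 3 - 1, iz = i / 9 - 1;
    bool isface = (std::abs(ix) + std::abs(iy) + std::abs(iz)) == 1;
    // flood this bg component (6-connectivity inside the 18-neighbourhood)
    std::queue<int> q; comp[i] = ncomp; q.push(i);
    bool touches = isface;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int j = 0; j < 27; ++j) {
        if (!in18[j] || nb[j] || comp[j] >= 0) continue;
        int jx = j % 3 - 1, jy = (j / 3) % 3 - 1, jz = j / 9 - 1;
        if (std::abs(jx - cx) + std::abs(jy - cy) + std::abs(jz - cz) == 1) {
          comp[j] = ncomp; q.push(j);
          if (std::abs(jx) + std::abs(jy) + std::abs(jz) == 1) touches = true;
        }
      }
    }
    if (touches) ; // counted below only if touching
    ncomp += touches ? 1 : 0;
    // mark non-touching comps too so they are not revisited (comp already set)
  }
  return ncomp;
}

static bool simple_point(const LogicalVector &mask, int x, int y, int z,
                         int nx, int ny, int nz) {
  bool nb[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = false;
        if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
          v = mask[idx3(xx, yy, zz, nx, ny)];
        nb[(dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)] = v;
      }
  return cc26_neigh(nb) == 1 && cc6_bg_neigh(nb) == 1;
}

static int fg_neighbours26(const LogicalVector &mask, int x, int y, int z,
                           int nx, int ny, int nz) {
  int cnt = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz &&
            mask[idx3(xx, yy, zz, nx, ny)]) ++cnt;
      }
  return cnt;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask_in, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  LogicalVector mask = clone(mask_in);
  NumericVector dt = cpp_edt3d(mask, dims); // distance of bg voxels is 0 here
  // we need distance of fg voxels to background: invert
  LogicalVector inv(n);
  for (int i = 0; i < n; ++i) inv[i] = !mask[i];
  NumericVector depth = cpp_edt3d(inv, dims);
  // directional sub-iterations: per sweep, six sub-sweeps each consider
  // only voxels whose face neighbour in that direction is background at
  // sub-sweep start (at most one voxel per column per sub-sweep, so
  // sequential removal cannot tunnel through a structure); candidates are
  // processed shallow-first with lexicographic tie-breaking and removed
  // only while still simple and not an endpoint.
  const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<std::pair<double, int> > cand;
      for (int i = 0; i < n; ++i) {
        if (!mask[i]) continue;
        int z = i / (nx * ny), rem = i % (nx * ny);
        int y = rem / nx, x = rem % nx;
        int xx = x + face[d][0], yy = y + face[d][1], zz = z + face[d][2];
        bool bg = xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
          zz >= nz || !mask[idx3(xx, yy, zz, nx, ny)];
        if (bg) cand.push_back(std::make_pair(depth[i], i));
      }
      std::sort(cand.begin(), cand.end());
      for (size_t c = 0; c < cand.size(); ++c) {
        int i = cand[c].second;
        if (!mask[i]) continue;
        int z = i / (nx * ny), rem = i % (nx * ny);
        int y = rem / nx, x = rem % nx;
        // two-sided border condition: deletable from direction d only
        // while the opposite face neighbour is still foreground, so a
        // sub-sweep cannot tunnel through a thin structure
        int xo = x - face[d][0], yo = y - face[d][1], zo = z - face[d][2];
        bool fg_opp = xo >= 0 && yo >= 0 && zo >= 0 && xo < nx && yo < ny &&
          zo < nz && mask[idx3(xo, yo, zo, nx, ny)];
        if (!fg_opp) continue;
        int nn = fg_neighbours26(mask, x, y, z, nx, ny, nz);
        if (nn <= 1) continue; // endpoint (or isolated voxel): keep
        if (simple_point(mask, x, y, z, nx, ny, nz)) {
          mask[i] = false;
          changed = true;
        }
      }
    }
  }
  (void)dt;
  return mask;
}

// A voxel is prunable when its foreground neighbours form exactly one
// 26-connected component: a curve endpoint, or a redundant corner voxel
// whose neighbours are mutually connected without it. Removal is
// sequential with re-verification, so a round can never disconnect the
// skeleton; isolated voxels (no neighbours) are kept.
static bool prunable(const LogicalVector &mask, int x, int y, int z,
                     int nx, int ny, int nz) {
  bool nb[27];
  int cnt = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = false;
        if (!(dx == 0 && dy == 0 && dz == 0) &&
            xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
          v = mask[idx3(xx, yy, zz, nx, ny)];
        nb[(dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)] = v;
        if (v) ++cnt;
      }
  nb[13] = false;
  // also require topological simplicity so that removing the voxel can
  // neither disconnect the skeleton nor open a tunnel (e.g. the centre of
  // a one-voxel-thick residual sheet patch)
  return cnt >= 1 && cc26_neigh(nb) == 1 && cc6_bg_neigh(nb) == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_prune_endpoints(LogicalVector mask_in, IntegerVector dims,
                                  int rounds) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  LogicalVector mask = clone(mask_in);
  std::vector<int> fg;
  for (int i = 0; i < n; ++i) if (mask[i]) fg.push_back(i);
  for (int r = 0; r < rounds; ++r) {
    std::vector<int> cand;
    for (size_t c = 0; c < fg.size(); ++c) {
      int i = fg[c];
      if (!mask[i]) continue;
      int z = i / (nx * ny), rem = i % (nx * ny);
      int y = rem / nx, x = rem % nx;
      if (prunable(mask, x, y, z, nx, ny, nz)) cand.push_back(i);
    }
    if (cand.empty()) break;
    bool removed = false;
    for (size_t c = 0; c < cand.size(); ++c) {
      int i = cand[c];
      int z = i / (nx * ny), rem = i % (nx * ny);
      int y = rem / nx, x = rem % nx;
      if (prunable(mask, x, y, z, nx, ny, nz)) { mask[i] = false; removed = true; }
    }
    if (!removed) break;
  }
  return mask;
}

// ---------------------------------------------------------------------------
// capsule voxelization: foreground iff the voxel centre lies within the
// linearly interpolated radius of a sub-segment centreline.

// [[Rcpp::export]]
LogicalVector cpp_voxelize(IntegerVector dims, double voxel, NumericVector origin,
                           NumericMatrix P, NumericMatrix Q,
                           NumericVector rp, NumericVector rq) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  for (int s = 0; s < P.nrow(); ++s) {
    double px = P(s,0), py = P(s,1), pz = P(s,2);
    double qx = Q(s,0), qy = Q(s,1), qz = Q(s,2);
    double r0 = rp[s], r1 = rq[s];
    double rmax = std::max(r0, r1);
    // bounding box in voxel indices
    int x0 = (int)std::floor((std::min(px,qx) - rmax - origin[0]) / voxel);
    int x1 = (int)std::ceil ((std::max(px,qx) + rmax - origin[0]) / voxel);
    int y0 = (int)std::floor((std::min(py,qy) - rmax - origin[1]) / voxel);
    int y1 = (int)std::ceil ((std::max(py,qy) + rmax - origin[1]) / voxel);
    int z0 = (int)std::floor((std::min(pz,qz) - rmax - origin[2]) / voxel);
    int z1 = (int)std::ceil ((std::max(pz,qz) + rmax - origin[2]) / voxel);
    x0 = std::max(x0, 0); y0 = std::max(y0, 0); z0 = std::max(z0, 0);
    x1 = std::min(x1, nx - 1); y1 = std::min(y1, ny - 1); z1 = std::min(z1, nz - 1);
    double vx = qx - px, vy = qy - py, vz = qz - pz;
    double L2 = vx*vx + vy*vy + vz*vz;
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double cx = origin[0] + x * voxel;
          double cy = origin[1] + y * voxel;
          double cz = origin[2] + z * voxel;
          double t = 0.0;
          if (L2 > 0)
            t = ((cx-px)*vx + (cy-py)*vy + (cz-pz)*vz) / L2;
          if (t < 0) t = 0; if (t > 1) t = 1;
          double ax = px + t*vx - cx, ay = py + t*vy - cy, az = pz + t*vz - cz;
          double d2 = ax*ax + ay*ay + az*az;
          double r = r0 + t * (r1 - r0);
          if (d2 <= r * r) out[idx3(x, y, z, nx, ny)] = true;
        }
  }
  return out;
}
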