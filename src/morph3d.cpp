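// 3D voxel morphology primitives: connected-component labelling (6/26),
// Euler characteristic of the cubical complex, medial-axis thinning, and an
// anisotropic chamfer distance transform. Arrays are logical/integer vectors
// with dim = c(nz, ny, nx), column-major as stored by R.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + (long long)ny * x);
}

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long long n = (long long)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<int> dz, dy, dx;
  for (int z = -1; z <= 1; ++z) for (int y = -1; y <= 1; ++y) for (int x = -1; x <= 1; ++x) {
    if (z == 0 && y == 0 && x == 0) continue;
    int m = std::abs(z) + std::abs(y) + std::abs(x);
    if (connectivity == 6 && m != 1) continue;
    dz.push_back(z); dy.push_back(y); dx.push_back(x);
  }
  int nn = dz.size();
  int cur = 0;
  std::vector<int> stack;
  for (int x0 = 0; x0 < nx; ++x0) for (int y0 = 0; y0 < ny; ++y0) for (int z0 = 0; z0 < nz; ++z0) {
    int i0 = idx3(z0, y0, x0, nz, ny);
    if (!mask[i0] || labels[i0]) continue;
    ++cur;
    labels[i0] = cur;
    stack.clear();
    stack.push_back(i0);
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      int x = i / (nz * ny), r = i % (nz * ny), y = r / nz, z = r % nz;
      for (int k = 0; k < nn; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int j = idx3(zz, yy, xx, nz, ny);
        if (mask[j] && !labels[j]) { labels[j] = cur; stack.push_back(j); }
      }
    }
  }
  labels.attr("dim") = dim;
  labels.attr("n_components") = cur;
  return labels;
}

// Euler characteristic of the union of closed unit cubes (one per foreground
// voxel): chi = V - E + F - C over distinct cells. This realisation connects
// diagonal foreground voxels (26-connectivity) and leaves the background
// 6-connected, the convention used throughout for Betti numbers.
// [[Rcpp::export(name = ".euler_characteristic_3d")]]
int euler_characteristic_3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int vz = nz + 1, vy = ny + 1, vx = nx + 1;
  long long nvert = (long long)vz * vy * vx;
  std::vector<char> vert(nvert, 0), ez(nvert, 0), ey(nvert, 0), ex(nvert, 0),
                    fz(nvert, 0), fy(nvert, 0), fx(nvert, 0);
  auto vi = [&](int z, int y, int x) { return (long long)z + vz * (y + (long long)vy * x); };
  long long ncube = 0;
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) for (int z = 0; z < nz; ++z) {
    if (!mask[idx3(z, y, x, nz, ny)]) continue;
    ++ncube;
    for (int az = 0; az < 2; ++az) for (int ay = 0; ay < 2; ++ay) for (int ax = 0; ax < 2; ++ax)
      vert[vi(z + az, y + ay, x + ax)] = 1;
    // edges: along z at the 4 (y,x) corners, etc.
    for (int ay = 0; ay < 2; ++ay) for (int ax = 0; ax < 2; ++ax) ez[vi(z, y + ay, x + ax)] = 1;
    for (int az = 0; az < 2; ++az) for (int ax = 0; ax < 2; ++ax) ey[vi(z + az, y, x + ax)] = 1;
    for (int az = 0; az < 2; ++az) for (int ay = 0; ay < 2; ++ay) ex[vi(z + az, y + ay, x)] = 1;
    // faces normal to z (spanned by y,x) at z and z+1, etc.
    for (int az = 0; az < 2; ++az) fz[vi(z + az, y, x)] = 1;
    for (int ay = 0; ay < 2; ++ay) fy[vi(z, y + ay, x)] = 1;
    for (int ax = 0; ax < 2; ++ax) fx[vi(z, y, x + ax)] = 1;
  }
  long long V = 0, E = 0, F = 0;
  for (long long i = 0; i < nvert; ++i) {
    V += vert[i]; E += ez[i] + ey[i] + ex[i]; F += fz[i] + fy[i] + fx[i];
  }
  return (int)(V - E + F - ncube);
}

// ---- simple-point machinery for thinning -----------------------------------

// neighborhood is a 27-long 0/1 array in (z,y,x) order with the center at 13.
static int count_fg26_components(const int *nb) {
  // 26-components of foreground among the 26 neighbors
  int comp[27]; for (int i = 0; i < 27; ++i) comp[i] = 0;
  int ncomp = 0;
  int stack[27], top;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || comp[s]) continue;
    ++ncomp; comp[s] = ncomp; top = 0; stack[top++] = s;
    while (top) {
      int i = stack[--top];
      int x = i / 9, y = (i % 9) / 3, z = i % 3;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
        int j = zz + 3 * yy + 9 * xx;
        if (j == 13 || j == i || !nb[j] || comp[j]) continue;
        comp[j] = ncomp; stack[top++] = j;
      }
    }
  }
  return ncomp;
}

static int count_bg6_components(const int *nb) {
  // 6-components of background within the 18-neighborhood (face+edge cells),
  // counting only components that contain a face neighbor of the center.
  int comp[27]; for (int i = 0; i < 27; ++i) comp[i] = 0;
  int ncomp = 0;
  int stack[27], top;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || nb[s] || comp[s]) continue;
    int x = s / 9, y = (s % 9) / 3, z = s % 3;
    int m = std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1);
    if (m != 1) continue; // seed only at face neighbors
    ++ncomp; comp[s] = ncomp; top = 0; stack[top++] = s;
    while (top) {
      int i = stack[--top];
      int xi = i / 9, yi = (i % 9) / 3, zi = i % 3;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int zz = zi + d6[k][0], yy = yi + d6[k][1], xx = xi + d6[k][2];
        if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
        int mm = std::abs(xx - 1) + std::abs(yy - 1) + std::abs(zz - 1);
        if (mm > 2) continue; // stay inside the 18-neighborhood
        int j = zz + 3 * yy + 9 * xx;
        if (j == 13 || nb[j] || comp[j]) continue;
        comp[j] = ncomp; stack[top++] = j;
      }
    }
  }
  return ncomp;
}

static inline void fill_neighborhood(const int *m, int nz, int ny, int nx,
                                     int z, int y, int x, int *nb) {
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) for (int dz = -1; dz <= 1; ++dz) {
    int zz = z + dz, yy = y + dy, xx = x + dx;
    int j = zz + 3 * 0; (void)j;
    int pos = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
    // outside the crop counts as foreground: objects cut by the volume
    // boundary keep full-length centerlines instead of receding caps
    if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) nb[pos] = 1;
    else nb[pos] = m[idx3(zz, yy, xx, nz, ny)];
    ++k;
  }
}

static inline bool is_simple(const int *nb) {
  return count_fg26_components(nb) == 1 && count_bg6_components(nb) == 1;
}

static inline int n26_count(const int *nb) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
  return c;
}

// Directional medial-axis thinning: 6 subiterations per pass, deleting simple,
// non-endpoint border points (sequential recheck preserves topology). Produces
// a 1-voxel curve skeleton for tubular objects.
// [[Rcpp::export(name = ".thin_3d")]]
LogicalVector thin_3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long long n = (long long)nz * ny * nx;
  std::vector<int> m(n);
  for (long long i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  const int dirs[6][3] = { // border direction offsets (dz,dy,dx)
    {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
  };
  int nb[27];
  bool changed = true;
  std::vector<long long> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) for (int z = 0; z < nz; ++z) {
        long long i = idx3(z, y, x, nz, ny);
        if (!m[i]) continue;
        int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
        int bg = 0; // outside the crop counts as foreground
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          bg = !m[idx3(zz, yy, xx, nz, ny)];
        if (!bg) continue;
        fill_neighborhood(m.data(), nz, ny, nx, z, y, x, nb);
        if (n26_count(nb) < 2) continue; // endpoint: keep
        if (is_simple(nb)) cand.push_back(i);
      }
      for (long long i : cand) { // sequential recheck
        int x = (int)(i / (nz * ny)); long long r = i % (nz * ny);
        int y = (int)(r / nz), z = (int)(r % nz);
        fill_neighborhood(m.data(), nz, ny, nx, z, y, x, nb);
        if (n26_count(nb) >= 2 && is_simple(nb)) { m[i] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (long long i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// Anisotropic chamfer distance to the background, in physical units.
// spacing = c(dz, dy, dx) in µm. Two-pass 26-neighborhood propagation.
// [[Rcpp::export(name = ".chamfer_dt_3d")]]
NumericVector chamfer_dt_3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long long n = (long long)nz * ny * nx;
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double big = 1e18;
  NumericVector d(n);
  for (long long i = 0; i < n; ++i) d[i] = mask[i] ? big : 0.0;
  // half-neighborhood offsets (lexicographically before center)
  std::vector<int> hz, hy, hx; std::vector<double> hw;
  for (int x = -1; x <= 1; ++x) for (int y = -1; y <= 1; ++y) for (int z = -1; z <= 1; ++z) {
    if (x > 0 || (x == 0 && (y > 0 || (y == 0 && z >= 0)))) continue;
    hz.push_back(z); hy.push_back(y); hx.push_back(x);
    hw.push_back(std::sqrt(z * sz * z * sz + y * sy * y * sy + x * sx * x * sx));
  }
  int nh = hz.size();
  // forward
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) for (int z = 0; z < nz; ++z) {
    long long i = idx3(z, y, x, nz, ny);
    if (d[i] == 0.0) continue;
    double best = d[i];
    for (int k = 0; k < nh; ++k) {
      int zz = z + hz[k], yy = y + hy[k], xx = x + hx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      double v = hw[k] + d[idx3(zz, yy, xx, nz, ny)];
      if (v < best) best = v;
    }
    d[i] = best;
  }
  // backward
  for (int x = nx - 1; x >= 0; --x) for (int y = ny - 1; y >= 0; --y) for (int z = nz - 1; z >= 0; --z) {
    long long i = idx3(z, y, x, nz, ny);
    if (d[i] == 0.0) continue;
    double best = d[i];
    for (int k = 0; k < nh; ++k) {
      int zz = z - hz[k], yy = y - hy[k], xx = x - hx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      double v = hw[k] + d[idx3(zz, yy, xx, nz, ny)];
      if (v < best) best = v;
    }
    d[i] = best;
  }
  d.attr("dim") = dim;
  return d;
}
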