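#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// ---- helpers ---------------------------------------------------------------

static inline int sub2ind(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// type-7 quantile on a sorted buffer
static double quantile7(const std::vector<double>& s, double p) {
  const int n = (int)s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return s[n - 1];
  double frac = h - lo;
  return s[lo] + frac * (s[lo + 1] - s[lo]);
}

// 13 unique 3D direction offsets (half of the 26-neighbourhood)
static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// ---- local window features (19 channels) -----------------------------------

// img: full volume (column-major, dims nx*ny*nz); vox: 0-based linear
// indices of lesion voxels; window: odd edge length. Masked-window
// convention: neighbourhood statistics use in-mask voxels only, and the
// window is truncated at image borders.
// [[Rcpp::export]]
NumericMatrix cpp_local_features(NumericVector img, IntegerVector mask,
                                 IntegerVector dims, IntegerVector vox,
                                 int window) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = window / 2;
  const int nv = vox.size();
  NumericMatrix out(nv, 19);
  std::vector<double> buf, srt;
  buf.reserve(window * window * window);

  for (int v = 0; v < nv; ++v) {
    int idx = vox[v];
    int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
    buf.clear();
    for (int dz = -r; dz <= r; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dy = -r; dy <= r; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        for (int dx = -r; dx <= r; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          int j = sub2ind(xx, yy, zz, nx, ny);
          if (mask[j] == 0) continue;
          buf.push_back(img[j]);
        }
      }
    }
    const int n = (int)buf.size();
    double s1 = 0, s2 = 0, mn = buf[0], mx = buf[0];
    for (int i = 0; i < n; ++i) {
      s1 += buf[i]; s2 += buf[i] * buf[i];
      if (buf[i] < mn) mn = buf[i];
      if (buf[i] > mx) mx = buf[i];
    }
    double mu = s1 / n;
    double range = mx - mn;

    srt = buf;
    std::sort(srt.begin(), srt.end());

    // 32-bin entropy over the window's own intensity range
    double ent = 0.0;
    if (range > 1e-24) {
      int hist[32] = {0};
      for (int i = 0; i < n; ++i) {
        int b = (int)(32.0 * (buf[i] - mn) / range);
        if (b > 31) b = 31;
        hist[b]++;
      }
      for (int b = 0; b < 32; ++b) {
        if (hist[b] > 0) {
          double p = (double)hist[b] / n;
          ent -= p * std::log2(p);
        }
      }
    }
    double p5  = quantile7(srt, 0.05), p10 = quantile7(srt, 0.10);
    double p25 = quantile7(srt, 0.25), p40 = quantile7(srt, 0.40);
    double p60 = quantile7(srt, 0.60), p75 = quantile7(srt, 0.75);
    double p90 = quantile7(srt, 0.90), p95 = quantile7(srt, 0.95);
    // trimmed means over the central 80% / 50% of the distribution
    double t10 = 0, t25 = 0; int n10 = 0, n25 = 0;
    for (int i = 0; i < n; ++i) {
      if (buf[i] >= p10 && buf[i] <= p90) { t10 += buf[i]; ++n10; }
      if (buf[i] >= p25 && buf[i] <= p75) { t25 += buf[i]; ++n25; }
    }
    t10 = n10 ? t10 / n10 : mu;
    t25 = n25 ? t25 / n25 : mu;

    out(v, 0)  = mu;
    out(v, 1)  = quantile7(srt, 0.5);
    out(v, 2)  = mn;
    out(v, 3)  = mx;
    out(v, 4)  = range;
    out(v, 5)  = p5;
    out(v, 6)  = p10;
    out(v, 7)  = p25;
    out(v, 8)  = p40;
    out(v, 9)  = p60;
    out(v, 10) = p75;
    out(v, 11) = p90;
    out(v, 12) = p95;
    out(v, 13) = t10;
    out(v, 14) = t25;
    out(v, 15) = (p25 + p75) / 2.0;
    out(v, 16) = (mn + mx) / 2.0;
    out(v, 17) = std::sqrt(s2 / n);
    out(v, 18) = ent;
  }
  return out;
}

// ---- exact Euclidean distance transform (squared, mm^2) --------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double s, int n) {
  // Felzenszwalb-Huttenlocher lower envelope with physical spacing s
  std::vector<int> vx(n);
  std::vector<double> zx(n + 1);
  int k = 0;
  vx[0] = 0; zx[0] = -std::numeric_limits<double>::infinity();
  zx[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = vx[k] * s;
      double sm = ((f[q] + xq * xq) - (f[vx[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sm <= zx[k]) { --k; }
      else {
        ++k; vx[k] = q; zx[k] = sm;
        zx[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (zx[k + 1] < xq) ++k;
    double xv = vx[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[vx[k]];
  }
}

// Squared Euclidean distance (mm^2) to the nearest nonzero voxel of mask.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;
  NumericVector D(mask.size());
  for (int i = 0; i < mask.size(); ++i) D[i] = mask[i] != 0 ? 0.0 : INF;

  std::vector<double> f, d;
  // x pass
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) f[x] = D[sub2ind(x, y, z, nx, ny)];
    dt1d(f, d, spacing[0], nx);
    for (int x = 0; x < nx; ++x) D[sub2ind(x, y, z, nx, ny)] = d[x];
  }
  // y pass
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) f[y] = D[sub2ind(x, y, z, nx, ny)];
    dt1d(f, d, spacing[1], ny);
    for (int y = 0; y < ny; ++y) D[sub2ind(x, y, z, nx, ny)] = d[y];
  }
  // z pass
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    for (int z = 0; z < nz; ++z) f[z] = D[sub2ind(x, y, z, nx, ny)];
    dt1d(f, d, spacing[2], nz);
    for (int z = 0; z < nz; ++z) D[sub2ind(x, y, z, nx, ny)] = d[z];
  }
  return D;
}

// ---- texture matrices (levels: 0 outside region, 1..Ng inside) -------------

// Symmetric GLCM aggregated (summed) over the 13 unique 3D directions,
// distance 1. Returns Ng x Ng counts.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector lv, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix P(ng, ng);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    int a = lv[sub2ind(x, y, z, nx, ny)];
    if (a == 0) continue;
    for (int d = 0; d < 13; ++d) {
      int xx = x + DIR13[d][0], yy = y + DIR13[d][1], zz = z + DIR13[d][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int b = lv[sub2ind(xx, yy, zz, nx, ny)];
      if (b == 0) continue;
      P(a - 1, b - 1) += 1.0;
      P(b - 1, a - 1) += 1.0;
    }
  }
  return P;
}

// GLRLM summed over 13 directions. Returns Ng x maxRunLength counts.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector lv, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxdim = std::max(nx, std::max(ny, nz));
  // diagonal runs can span up to the shortest side count, bounded by maxdim
  NumericMatrix R(ng, maxdim);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int a = lv[sub2ind(x, y, z, nx, ny)];
      if (a == 0) continue;
      // run start: predecessor out of bounds / out of region / different level
      int px = x - dx, py = y - dy, pz = z - dz;
      if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz) {
        if (lv[sub2ind(px, py, pz, nx, ny)] == a) continue;
      }
      int len = 1;
      int cx = x + dx, cy = y + dy, cz = z + dz;
      while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz &&
             lv[sub2ind(cx, cy, cz, nx, ny)] == a) {
        ++len; cx += dx; cy += dy; cz += dz;
      }
      R(a - 1, len - 1) += 1.0;
    }
  }
  return R;
}

// Connected zones of equal gray level (26-connectivity).
// Returns nzones x 2 matrix: (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector lv, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (lv[i] == 0 || seen[i]) continue;
    int level = lv[i], size = 0;
    stack.clear(); stack.push_back(i); seen[i] = 1;
    while (!stack.empty()) {
      int j = stack.back(); stack.pop_back();
      ++size;
      int x = j % nx, y = (j / nx) % ny, z = j / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int k = sub2ind(xx, yy, zz, nx, ny);
        if (!seen[k] && lv[k] == level) { seen[k] = 1; stack.push_back(k); }
      }
    }
    zl.push_back(level); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) { out(i, 0) = zl[i]; out(i, 1) = zs[i]; }
  return out;
}

// NGTDM over the 26-neighbourhood restricted to in-region voxels.
// Returns Ng x 2: (n_i voxels with >=1 valid neighbour, s_i sum |x - nbr mean|).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lv, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    int a = lv[sub2ind(x, y, z, nx, ny)];
    if (a == 0) continue;
    double sum = 0; int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      int xx = x + dx, yy = y + dy, zz = z + dz;
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int b = lv[sub2ind(xx, yy, zz, nx, ny)];
      if (b > 0) { sum += b; ++cnt; }
    }
    if (cnt > 0) {
      out(a - 1, 0) += 1.0;
      out(a - 1, 1) += std::fabs((double)a - sum / cnt);
    }
  }
  return out;
}

// GLDM: dependence = number of in-region 26-neighbours with |level diff| <= alpha.
// Returns Ng x 27 counts (column j = dependence j-1).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lv, IntegerVector dims, int ng, int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    int a = lv[sub2ind(x, y, z, nx, ny)];
    if (a == 0) continue;
    int dep = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      int xx = x + dx, yy = y + dy, zz = z + dz;
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int b = lv[sub2ind(xx, yy, zz, nx, ny)];
      if (b > 0 && std::abs(b - a) <= alpha) ++dep;
    }
    out(a - 1, dep) += 1.0;
  }
  return out;
}

// ---- isosurface (marching tetrahedra) --------------------------------------

// Cube corner offsets and a 6-tetrahedra decomposition sharing diagonal 0-6.
static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
static const int TETRA[6][4] = {
  {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}
};

static inline void interp_edge(const double p[4][3], const double v[4],
                               int a, int b, double iso, double out[3]) {
  double t = (iso - v[a]) / (v[b] - v[a]);
  for (int i = 0; i < 3; ++i) out[i] = p[a][i] + t * (p[b][i] - p[a][i]);
}

static double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3], w[3], cr[3];
  for (int i = 0; i < 3; ++i) { u[i] = b[i] - a[i]; w[i] = c[i] - a[i]; }
  cr[0] = u[1] * w[2] - u[2] * w[1];
  cr[1] = u[2] * w[0] - u[0] * w[2];
  cr[2] = u[0] * w[1] - u[1] * w[0];
  return 0.5 * std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
}

// Signed volume contribution of a triangle oriented so its normal points
// away from `inside` (divergence theorem; triangles sum to enclosed volume).
static double tri_signed_vol(double a[3], double b[3], double c[3],
                             const double inside[3]) {
  double u[3], w[3], n[3], cen[3];
  for (int i = 0; i < 3; ++i) {
    u[i] = b[i] - a[i]; w[i] = c[i] - a[i];
    cen[i] = (a[i] + b[i] + c[i]) / 3.0 - inside[i];
  }
  n[0] = u[1] * w[2] - u[2] * w[1];
  n[1] = u[2] * w[0] - u[0] * w[2];
  n[2] = u[0] * w[1] - u[1] * w[0];
  double dotp = n[0] * cen[0] + n[1] * cen[1] + n[2] * cen[2];
  if (dotp < 0) { // flip orientation
    std::swap(b[0], c[0]); std::swap(b[1], c[1]); std::swap(b[2], c[2]);
  }
  // det(a,b,c)/6
  double det =
    a[0] * (b[1] * c[2] - b[2] * c[1]) -
    a[1] * (b[0] * c[2] - b[2] * c[0]) +
    a[2] * (b[0] * c[1] - b[1] * c[0]);
  return det / 6.0;
}

// Trilinear sample of a field at voxel-index coordinates (x, y, z).
static double trilin(const NumericVector& f, int nx, int ny, int nz,
                     double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)x, y0 = (int)y, z0 = (int)z;
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double tx = x - x0, ty = y - y0, tz = z - z0;
  double c00 = f[sub2ind(x0,y0,z0,nx,ny)] * (1-tx) + f[sub2ind(x1,y0,z0,nx,ny)] * tx;
  double c10 = f[sub2ind(x0,y1,z0,nx,ny)] * (1-tx) + f[sub2ind(x1,y1,z0,nx,ny)] * tx;
  double c01 = f[sub2ind(x0,y0,z1,nx,ny)] * (1-tx) + f[sub2ind(x1,y0,z1,nx,ny)] * tx;
  double c11 = f[sub2ind(x0,y1,z1,nx,ny)] * (1-tx) + f[sub2ind(x1,y1,z1,nx,ny)] * tx;
  double c0 = c00 * (1-ty) + c10 * ty, c1 = c01 * (1-ty) + c11 * ty;
  return c0 * (1-tz) + c1 * tz;
}

// Orientation-corrected facet area: |A_i * (n_hat . N_hat)| where N_hat is
// the unit gradient of the smoothed indicator at the facet centroid.
// Projects staircase facets onto the underlying surface orientation.
static double tri_area_corr(const double a[3], const double b[3],
                            const double c[3], const NumericVector& nf,
                            int nx, int ny, int nz,
                            const NumericVector& spacing) {
  double u[3], w[3], n[3], cen[3];
  for (int i = 0; i < 3; ++i) {
    u[i] = b[i] - a[i]; w[i] = c[i] - a[i];
    cen[i] = (a[i] + b[i] + c[i]) / 3.0 / spacing[i];  // voxel units
  }
  n[0] = u[1] * w[2] - u[2] * w[1];
  n[1] = u[2] * w[0] - u[0] * w[2];
  n[2] = u[0] * w[1] - u[1] * w[0];   // |n| = 2 * area
  double g[3];
  const double h = 0.5;
  g[0] = (trilin(nf,nx,ny,nz,cen[0]+h,cen[1],cen[2]) -
          trilin(nf,nx,ny,nz,cen[0]-h,cen[1],cen[2])) / (2*h*spacing[0]);
  g[1] = (trilin(nf,nx,ny,nz,cen[0],cen[1]+h,cen[2]) -
          trilin(nf,nx,ny,nz,cen[0],cen[1]-h,cen[2])) / (2*h*spacing[1]);
  g[2] = (trilin(nf,nx,ny,nz,cen[0],cen[1],cen[2]+h) -
          trilin(nf,nx,ny,nz,cen[0],cen[1],cen[2]-h)) / (2*h*spacing[2]);
  double gn = std::sqrt(g[0]*g[0] + g[1]*g[1] + g[2]*g[2]);
  double raw = 0.5 * std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
  if (gn < 1e-12) return raw;
  return 0.5 * std::fabs(n[0]*g[0] + n[1]*g[1] + n[2]*g[2]) / gn;
}

// Surface of the `iso`-isosurface of a scalar field (caller pads with a
// below-iso border). Returns list(area, area_corrected, volume, vertices);
// vertices in physical mm. Marching tetrahedra with linear interpolation;
// `normal_field` (e.g. a smoothed indicator) drives the orientation-
// corrected area estimate.
// [[Rcpp::export]]
List cpp_mt_surface(NumericVector field, IntegerVector dims,
                    NumericVector spacing, double iso = 0.5,
                    Nullable<NumericVector> normal_field = R_NilValue) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  bool has_nf = normal_field.isNotNull();
  NumericVector nf;
  if (has_nf) nf = normal_field.get();
  double area = 0.0, area_corr = 0.0, volume = 0.0;
  std::vector<double> verts;
  double p[4][3], v[4], e0[3], e1[3], e2[3], e3[3];

  for (int z = 0; z < nz - 1; ++z) for (int y = 0; y < ny - 1; ++y)
  for (int x = 0; x < nx - 1; ++x) {
    double cv[8];
    int s = 0;
    for (int c = 0; c < 8; ++c) {
      cv[c] = field[sub2ind(x + CORNER[c][0], y + CORNER[c][1],
                            z + CORNER[c][2], nx, ny)];
      s += cv[c] > iso ? 1 : 0;
    }
    if (s == 0 || s == 8) continue;
    for (int t = 0; t < 6; ++t) {
      int in[4], nin = 0;
      for (int j = 0; j < 4; ++j) {
        int c = TETRA[t][j];
        p[j][0] = (x + CORNER[c][0]) * spacing[0];
        p[j][1] = (y + CORNER[c][1]) * spacing[1];
        p[j][2] = (z + CORNER[c][2]) * spacing[2];
        v[j] = cv[c];
        in[j] = cv[c] > iso ? 1 : 0;
        nin += in[j];
      }
      if (nin == 0 || nin == 4) continue;
      if (nin == 1 || nin == 3) {
        int tgt = (nin == 1) ? 1 : 0;   // the lone vertex
        int a = -1, o[3], no = 0;
        for (int j = 0; j < 4; ++j) {
          if (in[j] == tgt) a = j; else o[no++] = j;
        }
        interp_edge(p, v, a, o[0], iso, e0);
        interp_edge(p, v, a, o[1], iso, e1);
        interp_edge(p, v, a, o[2], iso, e2);
        area += tri_area(e0, e1, e2);
        area_corr += has_nf ? tri_area_corr(e0, e1, e2, nf, nx, ny, nz, spacing)
                            : tri_area(e0, e1, e2);
        double ref[3];
        if (nin == 1) {
          ref[0] = p[a][0]; ref[1] = p[a][1]; ref[2] = p[a][2];
        } else { // centroid of the three inside vertices
          ref[0] = ref[1] = ref[2] = 0;
          for (int j = 0; j < 3; ++j)
            for (int i = 0; i < 3; ++i) ref[i] += p[o[j]][i] / 3.0;
        }
        volume += tri_signed_vol(e0, e1, e2, ref);
        for (int i = 0; i < 3; ++i) verts.push_back(e0[i]);
        for (int i = 0; i < 3; ++i) verts.push_back(e1[i]);
        for (int i = 0; i < 3; ++i) verts.push_back(e2[i]);
      } else { // 2 in, 2 out -> quad
        int a2[2], o2[2], na = 0, no = 0;
        for (int j = 0; j < 4; ++j) {
          if (in[j]) a2[na++] = j; else o2[no++] = j;
        }
        interp_edge(p, v, a2[0], o2[0], iso, e0);
        interp_edge(p, v, a2[0], o2[1], iso, e1);
        interp_edge(p, v, a2[1], o2[1], iso, e2);
        interp_edge(p, v, a2[1], o2[0], iso, e3);
        area += tri_area(e0, e1, e2) + tri_area(e0, e2, e3);
        area_corr += has_nf
          ? tri_area_corr(e0, e1, e2, nf, nx, ny, nz, spacing) +
            tri_area_corr(e0, e2, e3, nf, nx, ny, nz, spacing)
          : tri_area(e0, e1, e2) + tri_area(e0, e2, e3);
        double ref[3];
        for (int i = 0; i < 3; ++i)
          ref[i] = (p[a2[0]][i] + p[a2[1]][i]) / 2.0;
        volume += tri_signed_vol(e0, e1, e2, ref);
        volume += tri_signed_vol(e0, e2, e3, ref);
        for (int i = 0; i < 3; ++i) verts.push_back(e0[i]);
        for (int i = 0; i < 3; ++i) verts.push_back(e1[i]);
        for (int i = 0; i < 3; ++i) verts.push_back(e2[i]);
        for (int i = 0; i < 3; ++i) verts.push_back(e3[i]);
      }
    }
  }
  int nv = (int)(verts.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) V(i, j) = verts[3 * i + j];
  return List::create(Named("area") = area,
                      Named("area_corrected") = area_corr,
                      Named("volume") = volume,
                      Named("vertices") = V);
}

// Maximum pairwise Euclidean distance between rows of pts (n x 3).
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d > best) best = d;
    }
  }
  return std::sqrt(best);
}
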