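// Voxel-level kernels: Euclidean distance transform, topology-preserving
// 3D thinning, 2D percentile filter, SOR Laplace solver, gradient
// streamline tracing, tube rasterization.  All arrays are R arrays in
// column-major order with dims (nx, ny, nz).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// ---------------------------------------------------------------------------
// 1D squared distance transform (Felzenszwalb & Huttenlocher), grid step h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -HUGE_VAL;
  z[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared EDT of the foreground (distance to nearest background voxel
// centre), anisotropic spacing.  Background voxels get 0.
// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite sentinel: HUGE_VAL would produce inf - inf = NaN in
  // the lower-envelope intersection arithmetic
  const double BIG = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = out[idx3(x, y, z, nx, ny)];
      dt1d(f, d, spacing[0], nx);
      for (int x = 0; x < nx; ++x) out[idx3(x, y, z, nx, ny)] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[idx3(x, y, z, nx, ny)];
      dt1d(f, d, spacing[1], ny);
      for (int y = 0; y < ny; ++y) out[idx3(x, y, z, nx, ny)] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[idx3(x, y, z, nx, ny)];
      dt1d(f, d, spacing[2], nz);
      for (int z = 0; z < nz; ++z) out[idx3(x, y, z, nx, ny)] = d[z];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test in the 3x3x3 neighbourhood (Malandain-Bertrand
// characterisation): deletable iff exactly one 26-component of foreground
// neighbours and exactly one 6-component of background within the
// 18-neighbourhood that is 6-adjacent to the centre.

// cube cell index c in 0..26 maps to offsets (c%3-1, c/3%3-1, c/9-1)
static int cube_dx(int c) { return c % 3 - 1; }
static int cube_dy(int c) { return (c / 3) % 3 - 1; }
static int cube_dz(int c) { return c / 9 - 1; }

static bool is_simple(const bool nb[27]) {
  // condition 1: one 26-connected foreground component among the 26 cells
  int labels[27];
  for (int i = 0; i < 27; ++i) labels[i] = -1;
  int ncomp_fg = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || labels[i] >= 0) continue;
    // BFS
    ++ncomp_fg;
    if (ncomp_fg > 1) return false;
    std::vector<int> stack;
    stack.push_back(i);
    labels[i] = ncomp_fg;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || j == c || !nb[j] || labels[j] >= 0) continue;
        if (std::abs(cube_dx(c) - cube_dx(j)) <= 1 &&
            std::abs(cube_dy(c) - cube_dy(j)) <= 1 &&
            std::abs(cube_dz(c) - cube_dz(j)) <= 1) {
          labels[j] = ncomp_fg;
          stack.push_back(j);
        }
      }
    }
  }
  if (ncomp_fg != 1) return false;

  // condition 2: 6-components of background restricted to the
  // 18-neighbourhood; count those containing a face neighbour of centre
  int blab[27];
  for (int i = 0; i < 27; ++i) blab[i] = -1;
  int ncomp_bg = 0;
  for (int i = 0; i < 27; ++i) {
    int md = std::abs(cube_dx(i)) + std::abs(cube_dy(i)) + std::abs(cube_dz(i));
    if (i == 13 || md > 2 || nb[i] || blab[i] >= 0) continue;
    ++ncomp_bg;
    bool touches_face = false;
    std::vector<int> stack;
    stack.push_back(i);
    blab[i] = ncomp_bg;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int mdc = std::abs(cube_dx(c)) + std::abs(cube_dy(c)) + std::abs(cube_dz(c));
      if (mdc == 1) touches_face = true;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || nb[j] || blab[j] >= 0) continue;
        int mdj = std::abs(cube_dx(j)) + std::abs(cube_dy(j)) + std::abs(cube_dz(j));
        if (mdj > 2) continue;
        int dd = std::abs(cube_dx(c) - cube_dx(j)) +
                 std::abs(cube_dy(c) - cube_dy(j)) +
                 std::abs(cube_dz(c) - cube_dz(j));
        if (dd == 1) {
          blab[j] = ncomp_bg;
          stack.push_back(j);
        }
      }
    }
    if (!touches_face) --ncomp_bg;  // not 6-adjacent to the centre: ignore
    else if (ncomp_bg > 1) return false;
  }
  return ncomp_bg == 1;
}

static void gather_neighbourhood(const std::vector<char>& fg, int x, int y,
                                 int z, int nx, int ny, int nz, bool nb[27]) {
  for (int c = 0; c < 27; ++c) {
    int xx = x + cube_dx(c), yy = y + cube_dy(c), zz = z + cube_dz(c);
    nb[c] = (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
                ? fg[idx3(xx, yy, zz, nx, ny)] != 0
                : false;
  }
}

static int count_nbr26(const bool nb[27]) {
  int cnt = 0;
  for (int c = 0; c < 27; ++c)
    if (c != 13 && nb[c]) ++cnt;
  return cnt;
}

// Curve thinning: sequential deletion of simple, non-endpoint border
// voxels in order of increasing distance-transform value (medial peel).
// Preserves 26-connectivity topology of the foreground.
// [[Rcpp::export(name = ".cpp_skeletonize")]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  NumericVector sp = NumericVector::create(1.0, 1.0, 1.0);
  NumericVector dist = cpp_edt(mask, dim, sp);

  bool nb[27];
  bool changed = true;
  std::vector<std::pair<double, R_xlen_t> > cand;
  while (changed) {
    changed = false;
    cand.clear();
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t i = idx3(x, y, z, nx, ny);
          if (!fg[i]) continue;
          // border: a 6-neighbour is background (or outside)
          bool border =
              x == 0 || fg[idx3(x - 1, y, z, nx, ny)] == 0 ||
              x == nx - 1 || fg[idx3(x + 1, y, z, nx, ny)] == 0 ||
              y == 0 || fg[idx3(x, y - 1, z, nx, ny)] == 0 ||
              y == ny - 1 || fg[idx3(x, y + 1, z, nx, ny)] == 0 ||
              z == 0 || fg[idx3(x, y, z - 1, nx, ny)] == 0 ||
              z == nz - 1 || fg[idx3(x, y, z + 1, nx, ny)] == 0;
          if (border) cand.push_back(std::make_pair(dist[i], i));
        }
    std::sort(cand.begin(), cand.end());
    for (size_t k = 0; k < cand.size(); ++k) {
      R_xlen_t i = cand[k].second;
      if (!fg[i]) continue;
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((R_xlen_t)nx * ny));
      gather_neighbourhood(fg, x, y, z, nx, ny, nz, nb);
      if (count_nbr26(nb) < 2) continue;  // endpoint or isolated: keep
      if (is_simple(nb)) {
        fg[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 2D percentile filter with a circular footprint (radius in pixels).
// percentile in [0,1]; linear-interpolated order statistic not needed:
// the kth smallest with k = ceil(p * m) is used (m = footprint size).
// [[Rcpp::export(name = ".cpp_rank_filter2d")]]
NumericMatrix cpp_rank_filter2d(NumericMatrix img, double radius,
                                double percentile) {
  int nx = img.nrow(), ny = img.ncol();
  std::vector<int> ox, oy;
  int ri = (int)std::floor(radius);
  for (int dy = -ri; dy <= ri; ++dy)
    for (int dx = -ri; dx <= ri; ++dx)
      if ((double)dx * dx + (double)dy * dy <= radius * radius) {
        ox.push_back(dx);
        oy.push_back(dy);
      }
  int m = (int)ox.size();
  NumericMatrix out(nx, ny);
  std::vector<double> vals;
  vals.reserve(m);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      vals.clear();
      for (int k = 0; k < m; ++k) {
        int xx = x + ox[k], yy = y + oy[k];
        if (xx >= 0 && yy >= 0 && xx < nx && yy < ny)
          vals.push_back(img(xx, yy));
      }
      int k = (int)std::ceil(percentile * vals.size()) - 1;
      if (k < 0) k = 0;
      std::nth_element(vals.begin(), vals.begin() + k, vals.end());
      out(x, y) = vals[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// SOR solver for the Laplace equation on an irregular domain.
// state: 0 = outside (no-flux), 1 = free, 2 = Dirichlet (value fixed).
// Neumann boundaries arise naturally by averaging over in-domain
// neighbours only.  Returns list(potential, iterations, max_update).
// [[Rcpp::export(name = ".cpp_sor_laplace")]]
List cpp_sor_laplace(NumericVector init, IntegerVector state,
                     IntegerVector dim, double omega, double tol,
                     int maxit) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector pot = clone(init);
  std::vector<R_xlen_t> free_idx;
  for (R_xlen_t i = 0; i < n; ++i)
    if (state[i] == 1) free_idx.push_back(i);

  double maxupd = HUGE_VAL;
  int it = 0;
  const int DX[6] = {-1, 1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, -1, 1, 0, 0};
  const int DZ[6] = {0, 0, 0, 0, -1, 1};
  while (it < maxit && maxupd > tol) {
    maxupd = 0.0;
    ++it;
    for (size_t k = 0; k < free_idx.size(); ++k) {
      R_xlen_t i = free_idx[k];
      int x = (int)(i % nx), y = (int)((i / nx) % ny),
          z = (int)(i / ((R_xlen_t)nx * ny));
      double s = 0.0;
      int cnt = 0;
      for (int d = 0; d < 6; ++d) {
        int xx = x + DX[d], yy = y + DY[d], zz = z + DZ[d];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t j = idx3(xx, yy, zz, nx, ny);
        if (state[j] == 0) continue;
        s += pot[j];
        ++cnt;
      }
      if (cnt == 0) continue;
      double newv = pot[i] + omega * (s / cnt - pot[i]);
      double upd = std::fabs(newv - pot[i]);
      if (upd > maxupd) maxupd = upd;
      pot[i] = newv;
    }
  }
  pot.attr("dim") = dim;
  return List::create(_["potential"] = pot, _["iterations"] = it,
                      _["max_update"] = maxupd);
}

// ---------------------------------------------------------------------------
// Ascending-gradient streamline tracing on the potential field.
// state: 0 outside cortex, 1 cortex, 2 cortex surface (target voxels).
// Per-voxel gradients precomputed by central differences restricted to
// in-cortex neighbours; trilinear interpolation over in-cortex corners.
// starts: 0-based voxel linear indices.  step in voxels.
// Returns matrix nstart x 4: hit position (0-based continuous voxel
// coords) and status (1 = resolved, 0 = unresolved).
// [[Rcpp::export(name = ".cpp_trace_streamlines")]]
NumericMatrix cpp_trace_streamlines(NumericVector pot, IntegerVector state,
                                    IntegerVector dim, IntegerVector starts,
                                    double step, int maxsteps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // gradient per cortex voxel
  std::vector<double> gx(n, 0.0), gy(n, 0.0), gz(n, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        if (state[i] == 0) continue;
        double c = pot[i];
        double lo, hi, den;
        // x
        lo = c; hi = c; den = 0.0;
        if (x > 0 && state[idx3(x - 1, y, z, nx, ny)] != 0) {
          lo = pot[idx3(x - 1, y, z, nx, ny)]; den += 1.0;
        }
        if (x < nx - 1 && state[idx3(x + 1, y, z, nx, ny)] != 0) {
          hi = pot[idx3(x + 1, y, z, nx, ny)]; den += 1.0;
        }
        gx[i] = den > 0 ? (hi - lo) / den : 0.0;
        lo = c; hi = c; den = 0.0;
        if (y > 0 && state[idx3(x, y - 1, z, nx, ny)] != 0) {
          lo = pot[idx3(x, y - 1, z, nx, ny)]; den += 1.0;
        }
        if (y < ny - 1 && state[idx3(x, y + 1, z, nx, ny)] != 0) {
          hi = pot[idx3(x, y + 1, z, nx, ny)]; den += 1.0;
        }
        gy[i] = den > 0 ? (hi - lo) / den : 0.0;
        lo = c; hi = c; den = 0.0;
        if (z > 0 && state[idx3(x, y, z - 1, nx, ny)] != 0) {
          lo = pot[idx3(x, y, z - 1, nx, ny)]; den += 1.0;
        }
        if (z < nz - 1 && state[idx3(x, y, z + 1, nx, ny)] != 0) {
          hi = pot[idx3(x, y, z + 1, nx, ny)]; den += 1.0;
        }
        gz[i] = den > 0 ? (hi - lo) / den : 0.0;
      }

  int ns = starts.size();
  NumericMatrix out(ns, 4);
  for (int s = 0; s < ns; ++s) {
    R_xlen_t i0 = starts[s];
    int x0 = (int)(i0 % nx), y0 = (int)((i0 / nx) % ny),
        z0 = (int)(i0 / ((R_xlen_t)nx * ny));
    double px = x0, py = y0, pz = z0;
    bool resolved = false;
    double lx = px, ly = py, lz = pz;
    bool last_was_surface = state[i0] == 2;
    if (last_was_surface) {
      resolved = true;
    } else {
      for (int t = 0; t < maxsteps; ++t) {
        // trilinear interpolation of the gradient over in-cortex corners
        int xf = (int)std::floor(px), yf = (int)std::floor(py),
            zf = (int)std::floor(pz);
        double fx = px - xf, fy = py - yf, fz = pz - zf;
        double vx = 0, vy = 0, vz = 0, wsum = 0;
        for (int c = 0; c < 8; ++c) {
          int xx = xf + (c & 1), yy = yf + ((c >> 1) & 1),
              zz = zf + ((c >> 2) & 1);
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          R_xlen_t j = idx3(xx, yy, zz, nx, ny);
          if (state[j] == 0) continue;
          double w = ((c & 1) ? fx : 1 - fx) * (((c >> 1) & 1) ? fy : 1 - fy) *
                     (((c >> 2) & 1) ? fz : 1 - fz);
          vx += w * gx[j];
          vy += w * gy[j];
          vz += w * gz[j];
          wsum += w;
        }
        if (wsum <= 0) break;
        vx /= wsum; vy /= wsum; vz /= wsum;
        double norm = std::sqrt(vx * vx + vy * vy + vz * vz);
        if (norm < 1e-12) break;
        px += step * vx / norm;
        py += step * vy / norm;
        pz += step * vz / norm;
        int xr = (int)std::lround(px), yr = (int)std::lround(py),
            zr = (int)std::lround(pz);
        int xc = std::min(std::max(xr, 0), nx - 1);
        int yc = std::min(std::max(yr, 0), ny - 1);
        int zc = std::min(std::max(zr, 0), nz - 1);
        bool outside_arr =
            xr != xc || yr != yc || zr != zc;
        R_xlen_t j = idx3(xc, yc, zc, nx, ny);
        if (!outside_arr && state[j] == 2) {
          resolved = true;
          lx = px; ly = py; lz = pz;
          break;
        }
        if (outside_arr || state[j] == 0) {
          // exited past the one-voxel surface shell (diagonal rounding
          // or array edge): accept when a surface voxel is 26-adjacent
          bool near_surface = last_was_surface;
          for (int dz = -1; dz <= 1 && !near_surface; ++dz)
            for (int dy = -1; dy <= 1 && !near_surface; ++dy)
              for (int dx = -1; dx <= 1 && !near_surface; ++dx) {
                int xx = xc + dx, yy = yc + dy, zz = zc + dz;
                if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                    zz >= nz)
                  continue;
                if (state[idx3(xx, yy, zz, nx, ny)] == 2) near_surface = true;
              }
          resolved = near_surface;
          if (resolved) { lx = px; ly = py; lz = pz; }
          break;
        }
        last_was_surface = false;
        lx = px; ly = py; lz = pz;
      }
    }
    out(s, 0) = lx;
    out(s, 1) = ly;
    out(s, 2) = lz;
    out(s, 3) = resolved ? 1.0 : 0.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rasterize tube sub-segments into a mask: voxel centres within radius of
// the sub-segment axis are set.  segs: rows (x1,y1,z1,x2,y2,z2,r) in um;
// spacing um/voxel; voxel centre of index (i,j,k) (0-based) is at
// ((i+0.5)*sx, ...).
// [[Rcpp::export(name = ".cpp_rasterize_tubes")]]
LogicalVector cpp_rasterize_tubes(NumericMatrix segs, IntegerVector dim,
                                  NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int s = 0; s < segs.nrow(); ++s) {
    double x1 = segs(s, 0), y1 = segs(s, 1), z1 = segs(s, 2);
    double x2 = segs(s, 3), y2 = segs(s, 4), z2 = segs(s, 5);
    double r = segs(s, 6);
    double r2 = r * r;
    int ix0 = std::max(0, (int)std::floor((std::min(x1, x2) - r) / sx - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil((std::max(x1, x2) + r) / sx));
    int iy0 = std::max(0, (int)std::floor((std::min(y1, y2) - r) / sy - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil((std::max(y1, y2) + r) / sy));
    int iz0 = std::max(0, (int)std::floor((std::min(z1, z2) - r) / sz - 0.5));
    int iz1 = std::min(nz - 1, (int)std::ceil((std::max(z1, z2) + r) / sz));
    double ux = x2 - x1, uy = y2 - y1, uz = z2 - z1;
    double L2 = ux * ux + uy * uy + uz * uz;
    for (int k = iz0; k <= iz1; ++k)
      for (int j = iy0; j <= iy1; ++j)
        for (int i = ix0; i <= ix1; ++i) {
          double cx = (i + 0.5) * sx, cy = (j + 0.5) * sy, cz = (k + 0.5) * sz;
          double wx = cx - x1, wy = cy - y1, wz = cz - z1;
          double t = L2 > 0 ? (wx * ux + wy * uy + wz * uz) / L2 : 0.0;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
          double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[idx3(i, j, k, nx, ny)] = true;
        }
  }
  out.attr("dim") = dim;
  return out;
}
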