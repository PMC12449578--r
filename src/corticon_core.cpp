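// Voxel-level primitives: separable convolution, block-mean downsampling,
// anisotropic Euclidean distance transforms, maximum-sphere local thickness,
// and signed distance to closed planar polygons.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// 1D convolution along one axis of a 3D array with a finite kernel.
// Boundary handling: kernel renormalised over in-range taps, so a constant
// field stays constant and interior voxels see the full (unit-sum) kernel.
// [[Rcpp::export]]
NumericVector cc_conv_axis(NumericVector vol, IntegerVector dim,
                           NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nk = kernel.size();
  const int hw = (nk - 1) / 2;  // kernel assumed odd-length, centred
  if (nk % 2 == 0) stop("kernel must have odd length");
  NumericVector out(vol.size());
  const double *v = vol.begin();
  double *o = out.begin();
  const double *kw = kernel.begin();

  const int n_axis = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  // strides
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;

  // iterate over all scanlines along `axis`
  const int n1 = (axis == 0) ? ny : nx;
  const int n2 = (axis == 2) ? ny : nz;
  std::vector<double> line(n_axis);
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      R_xlen_t base;
      if (axis == 0)      base = idx3(0, a, b, nx, ny);
      else if (axis == 1) base = idx3(a, 0, b, nx, ny);
      else                base = idx3(a, b, 0, nx, ny);
      for (int t = 0; t < n_axis; ++t) line[t] = v[base + stride * t];
      for (int t = 0; t < n_axis; ++t) {
        const int lo = std::max(-hw, -t);
        const int hi = std::min(hw, n_axis - 1 - t);
        double acc = 0.0, wsum = 0.0;
        for (int k = lo; k <= hi; ++k) {
          const double w = kw[k + hw];
          acc += w * line[t + k];
          wsum += w;
        }
        o[base + stride * t] = acc / wsum;
      }
    }
  }
  return out;
}

// Block-mean downsampling by integer factors (mass-conserving resampling).
// [[Rcpp::export]]
NumericVector cc_block_mean(NumericVector vol, IntegerVector dim,
                            IntegerVector factor) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int fx = factor[0], fy = factor[1], fz = factor[2];
  if (nx % fx || ny % fy || nz % fz) stop("dims not divisible by factors");
  const int mx = nx / fx, my = ny / fy, mz = nz / fz;
  NumericVector out((R_xlen_t)mx * my * mz);
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  const double *v = vol.begin();
  double *o = out.begin();
  const double inv = 1.0 / ((double)fx * fy * fz);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double acc = 0.0;
        for (int dk = 0; dk < fz; ++dk)
          for (int dj = 0; dj < fy; ++dj)
            for (int di = 0; di < fx; ++di)
              acc += v[idx3(i * fx + di, j * fy + dj, k * fz + dk, nx, ny)];
        o[idx3(i, j, k, mx, my)] = acc * inv;
      }
  return out;
}

// ---- Felzenszwalb-Huttenlocher 1D squared distance transform ----
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &vtx, std::vector<double> &zb,
                 int n, double step) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  vtx[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[vtx[0]] == INF) { k = 0; vtx[0] = q; zb[0] = -INF; zb[1] = INF; continue; }
    double s;
    while (true) {
      const int p = vtx[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    vtx[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < (double)q) ++k;
    const int p = vtx[k];
    d[q] = (f[p] == INF) ? INF : s2 * (q - p) * (double)(q - p) + f[p];
  }
}

// Squared Euclidean distance (physical units) from every voxel to the
// nearest background (mask == 0) voxel centre. Background voxels get 0.
// [[Rcpp::export]]
NumericVector cc_edt_sq(IntegerVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(mask.size());
  double *o = out.begin();
  for (R_xlen_t t = 0; t < mask.size(); ++t) o[t] = mask[t] ? INF : 0.0;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> vtx(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = o[idx3(i, j, k, nx, ny)];
      dt1d(f, d, vtx, zb, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) o[idx3(i, j, k, nx, ny)] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = o[idx3(i, j, k, nx, ny)];
      dt1d(f, d, vtx, zb, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) o[idx3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = o[idx3(i, j, k, nx, ny)];
      dt1d(f, d, vtx, zb, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) o[idx3(i, j, k, nx, ny)] = d[k];
    }
  return out;
}

static inline double cube_dist(double dx, double dy, double dz,
                               double hx, double hy, double hz) {
  const double ex = std::max(std::fabs(dx) - hx, 0.0);
  const double ey = std::max(std::fabs(dy) - hy, 0.0);
  const double ez = std::max(std::fabs(dz) - hz, 0.0);
  return std::sqrt(ex * ex + ey * ey + ez * ez);
}

// Maximum-sphere local thickness. Each in-mask voxel is labelled with the
// diameter (physical units) of the largest sphere that (a) lies entirely in
// the foreground -- radius = Euclidean distance from its centre voxel to the
// background REGION, i.e. the union of background voxel cubes -- and
// (b) contains the voxel's centre.
// When `centered` is true, each voxel is instead labelled with twice its own
// radius (largest sphere centred at the voxel), skipping the painting step.
// [[Rcpp::export]]
NumericVector cc_local_thickness(IntegerVector mask, IntegerVector dim,
                                 NumericVector spacing, bool centered = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double hx = sx / 2, hy = sy / 2, hz = sz / 2;
  const double halfdiag = std::sqrt(hx * hx + hy * hy + hz * hz);

  NumericVector edt2 = cc_edt_sq(mask, dim, spacing);

  R_xlen_t ntot = mask.size();
  bool any_bg = false;
  for (R_xlen_t t = 0; t < ntot; ++t) if (!mask[t]) { any_bg = true; break; }
  if (!any_bg) stop("mask has no background voxels");

  // centre-distance bounds: cube distance lies in [rc - halfdiag, rc]
  std::vector<double> rc(ntot, 0.0);
  for (R_xlen_t t = 0; t < ntot; ++t)
    if (mask[t]) rc[t] = std::sqrt(edt2[t]);

  // exact distance to the background region for every mask voxel
  std::vector<double> rad(ntot, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t t = idx3(i, j, k, nx, ny);
        if (!mask[t]) continue;
        // best-first shell traversal: start from the centre-distance upper
        // bound and prune whole planes/rows once their face distance
        // exceeds the best cube distance found so far (exact)
        const double rub = rc[t];                  // cube dist <= centre dist
        const int wx = (int)std::ceil((rub + halfdiag) / sx);
        const int wy = (int)std::ceil((rub + halfdiag) / sy);
        const int wz = (int)std::ceil((rub + halfdiag) / sz);
        double best2 = rub * rub + 1e-12;
        for (int mk = 0; mk <= wz; ++mk) {
          const double lz = std::max((mk - 0.5) * sz, 0.0);
          if (lz * lz > best2) break;
          for (int sk = 0; sk < (mk == 0 ? 1 : 2); ++sk) {
            const int dk = sk == 0 ? mk : -mk;
            const int kk = k + dk;
            const bool off_z = (kk < 0 || kk >= nz);
            for (int mj = 0; mj <= wy; ++mj) {
              const double ly = std::max((mj - 0.5) * sy, 0.0);
              if (lz * lz + ly * ly > best2) break;
              for (int sj = 0; sj < (mj == 0 ? 1 : 2); ++sj) {
                const int dj = sj == 0 ? mj : -mj;
                const int jj = j + dj;
                const bool off_y = (jj < 0 || jj >= ny);
                for (int mi = 0; mi <= wx; ++mi) {
                  const double lx = std::max((mi - 0.5) * sx, 0.0);
                  if (lz * lz + ly * ly + lx * lx > best2) break;
                  for (int si = 0; si < (mi == 0 ? 1 : 2); ++si) {
                    const int di = si == 0 ? mi : -mi;
                    const int ii = i + di;
                    const bool off_x = (ii < 0 || ii >= nx);
                    bool is_bg;
                    if (off_x || off_y || off_z) is_bg = true;
                    else is_bg = !mask[idx3(ii, jj, kk, nx, ny)];
                    if (!is_bg) continue;
                    const double d = cube_dist(di * sx, dj * sy, dk * sz,
                                               hx, hy, hz);
                    if (d * d < best2) best2 = d * d;
                  }
                }
              }
            }
          }
        }
        rad[t] = std::sqrt(best2);
      }

  if (centered) {
    NumericVector lab(ntot);
    for (R_xlen_t t = 0; t < ntot; ++t) lab[t] = 2.0 * rad[t];
    lab.attr("dim") = dim;
    return lab;
  }

  // dominated-sphere pruning (exact): sphere(c, r) lies inside
  // sphere(c', r') whenever |c - c'| + r <= r', so it can never change a
  // label and need not be painted. Domination chains terminate because the
  // dominating radius is strictly larger (|c - c'| > 0).
  std::vector<char> keep(ntot, 1);
  const int DW = 3;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t t = idx3(i, j, k, nx, ny);
        if (!mask[t]) { keep[t] = 0; continue; }
        bool dominated = false;
        for (int dk = -DW; dk <= DW && !dominated; ++dk) {
          const int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -DW; dj <= DW && !dominated; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            for (int di = -DW; di <= DW; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              if (di == 0 && dj == 0 && dk == 0) continue;
              const R_xlen_t u = idx3(ii, jj, kk, nx, ny);
              if (!mask[u]) continue;
              const double d = std::sqrt(di * sx * (double)di * sx +
                                         dj * sy * (double)dj * sy +
                                         dk * sz * (double)dk * sz);
              if (rad[u] >= rad[t] + d) { dominated = true; break; }
            }
          }
        }
        if (dominated) keep[t] = 0;
      }

  // paint: process sphere centres by descending radius
  std::vector<R_xlen_t> order;
  order.reserve(ntot / 4);
  for (R_xlen_t t = 0; t < ntot; ++t)
    if (mask[t] && keep[t] && rad[t] > 0) order.push_back(t);
  std::sort(order.begin(), order.end(),
            [&rad](R_xlen_t a, R_xlen_t b) { return rad[a] > rad[b]; });

  NumericVector lab(ntot);
  double *L = lab.begin();
  for (R_xlen_t t = 0; t < ntot; ++t) L[t] = 0.0;

  for (R_xlen_t oi = 0; oi < (R_xlen_t)order.size(); ++oi) {
    const R_xlen_t t = order[oi];
    const double r = rad[t];
    const double dia = 2.0 * r;
    const int k = (int)(t / ((R_xlen_t)nx * ny));
    const int j = (int)((t / nx) % ny);
    const int i = (int)(t % nx);
    const int wx = (int)std::floor(r / sx);
    const int wy = (int)std::floor(r / sy);
    const int wz = (int)std::floor(r / sz);
    const double r2 = r * r + 1e-12;
    for (int dk = -wz; dk <= wz; ++dk) {
      const int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      const double zz = dk * sz * (double)dk * sz;
      for (int dj = -wy; dj <= wy; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        const double yy = dj * sy * (double)dj * sy;
        if (zz + yy > r2) continue;
        for (int di = -wx; di <= wx; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          const double dd = zz + yy + di * sx * (double)di * sx;
          if (dd > r2) continue;
          const R_xlen_t u = idx3(ii, jj, kk, nx, ny);
          if (mask[u] && L[u] < dia) L[u] = dia;
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Signed Euclidean distance from query points to a closed polygon given by
// vertices (px, py) in order (closing edge added implicitly).
// Positive outside the polygon, negative inside (even-odd rule).
// [[Rcpp::export]]
NumericVector cc_polygon_signed_distance(NumericVector px, NumericVector py,
                                         NumericVector qx, NumericVector qy) {
  const int nv = px.size();
  const R_xlen_t nq = qx.size();
  if (nv < 3) stop("polygon needs >= 3 vertices");
  NumericVector out(nq);
  for (R_xlen_t q = 0; q < nq; ++q) {
    const double x = qx[q], y = qy[q];
    double best2 = std::numeric_limits<double>::infinity();
    bool inside = false;
    for (int a = 0, b = nv - 1; a < nv; b = a++) {
      const double ax = px[a], ay = py[a], bx = px[b], by = py[b];
      // point-segment squared distance
      const double ex = bx - ax, ey = by - ay;
      const double len2 = ex * ex + ey * ey;
      double tt = (len2 > 0) ? ((x - ax) * ex + (y - ay) * ey) / len2 : 0.0;
      tt = std::max(0.0, std::min(1.0, tt));
      const double cx = ax + tt * ex - x, cy = ay + tt * ey - y;
      const double d2 = cx * cx + cy * cy;
      if (d2 < best2) best2 = d2;
      // even-odd crossing test
      if ((ay > y) != (by > y)) {
        const double xi = ax + (y - ay) / (by - ay) * (bx - ax);
        if (x < xi) inside = !inside;
      }
    }
    out[q] = (inside ? -1.0 : 1.0) * std::sqrt(best2);
  }
  return out;
}
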