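#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear interpolation at fractional (0-based) indices; NA if any of the
// four surrounding nodes is NA or the query is outside the matrix.
// [[Rcpp::export]]
NumericVector bilinear_cpp(NumericMatrix m, NumericVector fx, NumericVector fy) {
  int n = fx.size();
  int nx = m.nrow(), ny = m.ncol();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double x = fx[k], y = fy[k];
    if (!(x >= 0.0) || !(y >= 0.0) || x > nx - 1 || y > ny - 1) {
      out[k] = NA_REAL;
      continue;
    }
    int i = (int)std::floor(x), j = (int)std::floor(y);
    if (i >= nx - 1) i = nx - 2;
    if (j >= ny - 1) j = ny - 2;
    if (nx == 1) i = 0;
    if (ny == 1) j = 0;
    double tx = x - i, ty = y - j;
    double v00 = m(i, j);
    double v10 = (nx > 1) ? m(i + 1, j) : v00;
    double v01 = (ny > 1) ? m(i, j + 1) : v00;
    double v11 = (nx > 1 && ny > 1) ? m(i + 1, j + 1) : v00;
    if (ISNAN(v00) || ISNAN(v10) || ISNAN(v01) || ISNAN(v11)) {
      out[k] = NA_REAL;
      continue;
    }
    out[k] = v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
             v01 * (1 - tx) * ty + v11 * tx * ty;
  }
  return out;
}

// Mean of grid pixels whose centres fall inside the square aperture
// [cx-half, cx+half] x [cy-half, cy+half] (closed with a tiny epsilon).
// [[Rcpp::export]]
NumericVector aperture_mean_cpp(NumericMatrix m, NumericVector origin,
                                NumericVector spacing, NumericVector cx,
                                NumericVector cy, double half) {
  int n = cx.size();
  int nx = m.nrow(), ny = m.ncol();
  const double eps = 1e-9;
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    int i0 = (int)std::ceil((cx[k] - half - origin[0]) / spacing[0] - eps);
    int i1 = (int)std::floor((cx[k] + half - origin[0]) / spacing[0] + eps);
    int j0 = (int)std::ceil((cy[k] - half - origin[1]) / spacing[1] - eps);
    int j1 = (int)std::floor((cy[k] + half - origin[1]) / spacing[1] + eps);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    double s = 0.0;
    long cnt = 0;
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        s += m(i, j);
        ++cnt;
      }
    out[k] = cnt > 0 ? s / cnt : NA_REAL;
  }
  return out;
}

// 2D gamma search: for each reference point, minimum of
// sqrt(dist^2/dta^2 + (D_eval - D_ref)^2/dd_abs^2) over the fine evaluated
// grid within the search-radius cap. Rows/columns are visited centre-out so
// the distance term allows early termination. NA evaluated cells are
// skipped; if no candidate exists the result is NA.
// [[Rcpp::export]]
NumericVector gamma_search_cpp(NumericVector rx, NumericVector ry,
                               NumericVector rd, NumericVector dd_abs,
                               NumericMatrix ev, NumericVector ev_origin,
                               double step, double dta, double cap) {
  int np = rx.size();
  int nx = ev.nrow(), ny = ev.ncol();
  double dta2 = dta * dta;
  NumericVector out(np);
  int w = (int)std::ceil(cap / step);
  for (int p = 0; p < np; ++p) {
    double x = rx[p], y = ry[p], d = rd[p];
    double da = dd_abs[p];
    double cxi = (x - ev_origin[0]) / step;
    double cyi = (y - ev_origin[1]) / step;
    int ic = (int)std::lround(cxi), jc = (int)std::lround(cyi);
    double best = R_PosInf;
    for (int ring = 0; ring <= w; ++ring) {
      // columns at |i - ic| == ring (both sides); ring 0 is the centre column
      bool any_row = false;
      for (int side = 0; side < (ring == 0 ? 1 : 2); ++side) {
        int i = (side == 0) ? ic - ring : ic + ring;
        if (i < 0 || i >= nx) continue;
        double dx = ev_origin[0] + i * step - x;
        double tx = dx * dx / dta2;
        if (tx >= best) continue;
        any_row = true;
        for (int jr = 0; jr <= w; ++jr) {
          bool advanced = false;
          for (int jside = 0; jside < (jr == 0 ? 1 : 2); ++jside) {
            int j = (jside == 0) ? jc - jr : jc + jr;
            if (j < 0 || j >= ny) continue;
            double dy = ev_origin[1] + j * step - y;
            double r2 = tx + dy * dy / dta2;
            if (r2 >= best || dx * dx + dy * dy > cap * cap + 1e-12) continue;
            advanced = true;
            double v = ev(i, j);
            if (ISNAN(v)) continue;
            double dd = (v - d) / da;
            double g2 = r2 + dd * dd;
            if (g2 < best) best = g2;
          }
          if (!advanced && jr > 0) {
            // both sides of this row ring exceed the current best or the cap
            double dymin = (jr - 1) * step;
            if (tx + dymin * dymin / dta2 >= best) break;
          }
        }
      }
      if (!any_row && ring > 0) {
        double dxmin = (ring - 1) * step;
        if (dxmin * dxmin / dta2 >= best) break;
      }
    }
    out[p] = R_FINITE(best) ? std::sqrt(best) : NA_REAL;
  }
  return out;
}

// 3D gamma search on voxel grids (small blocks); brute force with row-level
// pruning, per-axis step sizes.
// [[Rcpp::export]]
NumericVector gamma_search3d_cpp(NumericVector rx, NumericVector ry,
                                 NumericVector rz, NumericVector rd,
                                 NumericVector dd_abs, NumericVector ev,
                                 IntegerVector dims, NumericVector ev_origin,
                                 NumericVector step, double dta, double cap) {
  int np = rx.size();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double dta2 = dta * dta, cap2 = cap * cap;
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf;
    int i0 = std::max(0, (int)std::ceil((rx[p] - cap - ev_origin[0]) / step[0]));
    int i1 = std::min(nx - 1, (int)std::floor((rx[p] + cap - ev_origin[0]) / step[0]));
    int j0 = std::max(0, (int)std::ceil((ry[p] - cap - ev_origin[1]) / step[1]));
    int j1 = std::min(ny - 1, (int)std::floor((ry[p] + cap - ev_origin[1]) / step[1]));
    int k0 = std::max(0, (int)std::ceil((rz[p] - cap - ev_origin[2]) / step[2]));
    int k1 = std::min(nz - 1, (int)std::floor((rz[p] + cap - ev_origin[2]) / step[2]));
    for (int i = i0; i <= i1; ++i) {
      double dx = ev_origin[0] + i * step[0] - rx[p];
      double tx = dx * dx;
      if (tx / dta2 >= best) continue;
      for (int j = j0; j <= j1; ++j) {
        double dy = ev_origin[1] + j * step[1] - ry[p];
        double txy = tx + dy * dy;
        if (txy / dta2 >= best || txy > cap2) continue;
        for (int k = k0; k <= k1; ++k) {
          double dz = ev_origin[2] + k * step[2] - rz[p];
          double r2 = txy + dz * dz;
          if (r2 > cap2 || r2 / dta2 >= best) continue;
          double v = ev[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
          if (ISNAN(v)) continue;
          double dd = (v - rd[p]) / dd_abs[p];
          double g2 = r2 / dta2 + dd * dd;
          if (g2 < best) best = g2;
        }
      }
    }
    out[p] = R_FINITE(best) ? std::sqrt(best) : NA_REAL;
  }
  return out;
}

// Expand a (possibly 45-degree-rotated) lattice onto a plain-frame fine
// grid by bilinear interpolation; avoids materialising per-node coordinate
// vectors in R. Returns NA outside the lattice or next to missing sites.
// [[Rcpp::export]]
NumericMatrix lattice_fine_cpp(NumericMatrix lat, double ox, double dx,
                               double oy, double dy, bool rotated,
                               double fx0, double fy0, double step,
                               int nx, int ny) {
  NumericMatrix out(nx, ny);
  int lx = lat.nrow(), ly = lat.ncol();
  const double inv_sqrt2 = 0.7071067811865476;
  for (int j = 0; j < ny; ++j) {
    double y = fy0 + j * step;
    for (int i = 0; i < nx; ++i) {
      double x = fx0 + i * step;
      double u = x, v = y;
      if (rotated) {
        u = (x + y) * inv_sqrt2;
        v = (y - x) * inv_sqrt2;
      }
      double fi = (u - ox) / dx;
      double fj = (v - oy) / dy;
      if (!(fi >= 0.0) || !(fj >= 0.0) || fi > lx - 1 || fj > ly - 1) {
        out(i, j) = NA_REAL;
        continue;
      }
      int a = (int)std::floor(fi), b = (int)std::floor(fj);
      if (a >= lx - 1) a = lx - 2;
      if (b >= ly - 1) b = ly - 2;
      if (lx == 1) a = 0;
      if (ly == 1) b = 0;
      double tx = fi - a, ty = fj - b;
      double v00 = lat(a, b);
      double v10 = (lx > 1) ? lat(a + 1, b) : v00;
      double v01 = (ly > 1) ? lat(a, b + 1) : v00;
      double v11 = (lx > 1 && ly > 1) ? lat(a + 1, b + 1) : v00;
      if (ISNAN(v00) || ISNAN(v10) || ISNAN(v01) || ISNAN(v11)) {
        out(i, j) = NA_REAL;
        continue;
      }
      out(i, j) = v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
                  v01 * (1 - tx) * ty + v11 * tx * ty;
    }
  }
  return out;
}
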