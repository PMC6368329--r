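#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Uniform-grid spatial index over 2D points. Cell size equals the query
// radius, so every ball query touches at most the 3x3 cell neighborhood.
// Queries are exact (no approximate neighbors): every point within the
// stated radius is returned.
struct Grid2D {
  const std::vector<double>& x;
  const std::vector<double>& y;
  double cell, minx, miny;
  std::unordered_map<long long, std::vector<int> > cells;

  Grid2D(const std::vector<double>& x_, const std::vector<double>& y_,
         double cell_) : x(x_), y(y_), cell(cell_) {
    minx = std::numeric_limits<double>::infinity();
    miny = std::numeric_limits<double>::infinity();
    for (size_t i = 0; i < x.size(); ++i) {
      if (x[i] < minx) minx = x[i];
      if (y[i] < miny) miny = y[i];
    }
    if (!std::isfinite(minx)) { minx = 0.0; miny = 0.0; }
    if (!(cell > 0.0) || !std::isfinite(cell)) cell = 1.0;
    for (size_t i = 0; i < x.size(); ++i)
      cells[key(x[i], y[i])].push_back((int)i);
  }

  long long key(double px, double py) const {
    long long cx = (long long)std::floor((px - minx) / cell);
    long long cy = (long long)std::floor((py - miny) / cell);
    return cx * 2097152LL + cy; // 2^21 stride; fields are << 2^21 cells wide
  }

  // indices of points with distance <= r from (px, py)
  void query(double px, double py, double r, std::vector<int>& out) const {
    out.clear();
    double r2 = r * r;
    long long cx = (long long)std::floor((px - minx) / cell);
    long long cy = (long long)std::floor((py - miny) / cell);
    long long reach = (long long)std::ceil(r / cell);
    for (long long dx = -reach; dx <= reach; ++dx) {
      for (long long dy = -reach; dy <= reach; ++dy) {
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
          cells.find((cx + dx) * 2097152LL + (cy + dy));
        if (it == cells.end()) continue;
        for (size_t k = 0; k < it->second.size(); ++k) {
          int j = it->second[k];
          double ddx = x[j] - px, ddy = y[j] - py;
          if (ddx * ddx + ddy * ddy <= r2) out.push_back(j);
        }
      }
    }
  }
};

static std::vector<double> as_vec(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

// Exact nearest-neighbor distances from each query point to the reference
// set. With exclude_self = TRUE, query i and reference i are the same point
// and are skipped (sets must be index-aligned).
// [[Rcpp::export]]
NumericVector cpp_nnd(NumericVector qx, NumericVector qy,
                      NumericVector rx, NumericVector ry,
                      bool exclude_self) {
  int nq = qx.size(), nr = rx.size();
  NumericVector out(nq);
  std::vector<double> rxx = as_vec(rx), ryy = as_vec(ry);

  // starting cell size: guess from bounding box density, grow until a hit
  double minx = R_PosInf, maxx = R_NegInf, miny = R_PosInf, maxy = R_NegInf;
  for (int j = 0; j < nr; ++j) {
    minx = std::min(minx, rxx[j]); maxx = std::max(maxx, rxx[j]);
    miny = std::min(miny, ryy[j]); maxy = std::max(maxy, ryy[j]);
  }
  double span = std::max(maxx - minx, maxy - miny);
  double cell = span > 0 ? span / std::max(1.0, std::sqrt((double)nr)) : 1.0;
  Grid2D grid(rxx, ryy, cell);

  std::vector<int> hits;
  for (int i = 0; i < nq; ++i) {
    // a search radius reaching the farthest bounding-box corner is
    // guaranteed to see every reference point
    double fx = std::max(std::abs(qx[i] - minx), std::abs(qx[i] - maxx));
    double fy = std::max(std::abs(qy[i] - miny), std::abs(qy[i] - maxy));
    double rmax = std::sqrt(fx * fx + fy * fy) * (1.0 + 1e-12) + 1e-9;
    double best2 = R_PosInf;
    double r = cell;
    while (true) {
      grid.query(qx[i], qy[i], r, hits);
      best2 = R_PosInf;
      for (size_t k = 0; k < hits.size(); ++k) {
        int j = hits[k];
        if (exclude_self && j == i) continue;
        double dx = rxx[j] - qx[i], dy = ryy[j] - qy[i];
        double d2 = dx * dx + dy * dy;
        if (d2 < best2) best2 = d2;
      }
      // a hit at distance <= r is definitive; otherwise widen the search
      if (best2 <= r * r) break;
      if (r >= rmax) break; // the whole reference set has been scanned
      r = std::min(r * 2.0, rmax);
    }
    out[i] = std::isfinite(best2) ? std::sqrt(best2) : NA_REAL;
  }
  return out;
}

// Counts of reference points within each of K closed balls around every
// query point. Returns an nq x K integer matrix; radii must be increasing.
// [[Rcpp::export]]
IntegerMatrix cpp_count_within(NumericVector qx, NumericVector qy,
                               NumericVector rx, NumericVector ry,
                               NumericVector radii, bool exclude_self) {
  int nq = qx.size(), K = radii.size();
  std::vector<double> rxx = as_vec(rx), ryy = as_vec(ry);
  double rmax = radii[K - 1];
  Grid2D grid(rxx, ryy, rmax);
  IntegerMatrix out(nq, K);
  std::vector<int> hits;
  std::vector<double> r2(K);
  for (int k = 0; k < K; ++k) r2[k] = radii[k] * radii[k];

  for (int i = 0; i < nq; ++i) {
    grid.query(qx[i], qy[i], rmax, hits);
    for (size_t h = 0; h < hits.size(); ++h) {
      int j = hits[h];
      if (exclude_self && j == i) continue;
      double dx = rxx[j] - qx[i], dy = ryy[j] - qy[i];
      double d2 = dx * dx + dy * dy;
      // smallest radius containing this point; increment all larger
      for (int k = 0; k < K; ++k) {
        if (d2 <= r2[k]) { for (int m = k; m < K; ++m) out(i, m)++; break; }
      }
    }
  }
  return out;
}

// Deterministic DBSCAN. Core point: >= min_pts neighbors within eps,
// counting itself. Clusters are connected components of core points;
// border (non-core) points join the cluster of the lowest-index core point
// within eps. Labels: 0 = noise, clusters numbered 1..k in order of their
// lowest core-point index.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y,
                         double eps, int min_pts) {
  int n = x.size();
  std::vector<double> xx = as_vec(x), yy = as_vec(y);
  Grid2D grid(xx, yy, eps);
  std::vector<int> hits;

  std::vector<bool> core(n, false);
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    grid.query(xx[i], yy[i], eps, hits);
    nb[i] = hits;
    core[i] = (int)hits.size() >= min_pts;
  }

  IntegerVector label(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || label[i] != 0) continue;
    ++next;
    label[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      for (size_t k = 0; k < nb[p].size(); ++k) {
        int q = nb[p][k];
        if (core[q] && label[q] == 0) { label[q] = next; stack.push_back(q); }
      }
    }
  }
  // border points: lowest-index claiming core
  for (int i = 0; i < n; ++i) {
    if (core[i]) continue;
    int best = -1;
    for (size_t k = 0; k < nb[i].size(); ++k) {
      int q = nb[i][k];
      if (core[q] && (best < 0 || q < best)) best = q;
    }
    label[i] = best >= 0 ? label[best] : 0;
  }
  return label;
}

// Variable-bandwidth mean-shift with Gaussian kernels truncated at
// trunc * max(h_x, h_y) of each contributing data point. Each point's mean
// iterates until the shift falls below tol or max_iter is reached.
// Returns modes (n x 2), iteration counts and convergence flags.
// [[Rcpp::export]]
List cpp_mean_shift(NumericVector x, NumericVector y,
                    NumericVector hx, NumericVector hy,
                    double trunc_factor, double tol, int max_iter) {
  int n = x.size();
  std::vector<double> xx = as_vec(x), yy = as_vec(y);

  bool truncated = std::isfinite(trunc_factor);
  double hmax = 0.0;
  for (int j = 0; j < n; ++j) hmax = std::max(hmax, std::max(hx[j], hy[j]));
  double qr = truncated ? trunc_factor * hmax : 0.0;

  Grid2D grid(xx, yy, truncated ? qr : 1.0);
  std::vector<int> hits;

  NumericMatrix modes(n, 2);
  IntegerVector iters(n);
  LogicalVector conv(n);
  double tol2 = tol * tol;

  for (int i = 0; i < n; ++i) {
    double mx = xx[i], my = yy[i];
    int it = 0;
    bool ok = false;
    for (it = 0; it < max_iter; ++it) {
      double sw = 0.0, sx = 0.0, sy = 0.0;
      if (truncated) grid.query(mx, my, qr, hits);
      else { hits.resize(n); for (int j = 0; j < n; ++j) hits[j] = j; }
      for (size_t k = 0; k < hits.size(); ++k) {
        int j = hits[k];
        double dx = xx[j] - mx, dy = yy[j] - my;
        if (truncated) {
          double rj = trunc_factor * std::max(hx[j], hy[j]);
          if (dx * dx + dy * dy > rj * rj) continue;
        }
        double ux = dx / hx[j], uy = dy / hy[j];
        double w = std::exp(-0.5 * (ux * ux + uy * uy));
        sw += w; sx += w * xx[j]; sy += w * yy[j];
      }
      if (sw <= 0.0) { ok = true; break; } // no support: mean is stationary
      double nx = sx / sw, ny = sy / sw;
      double shift2 = (nx - mx) * (nx - mx) + (ny - my) * (ny - my);
      mx = nx; my = ny;
      if (shift2 < tol2) { ok = true; ++it; break; }
    }
    modes(i, 0) = mx; modes(i, 1) = my;
    iters[i] = it;
    conv[i] = ok;
  }
  return List::create(_["modes"] = modes, _["iterations"] = iters,
                      _["converged"] = conv);
}
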