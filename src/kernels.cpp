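// Compiled kernels for 3D image operations on column-major arrays
// with dim = (nz, ny, nx); linear index = z + nz*(y + ny*x).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t IDX(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Separable 1D convolution along one axis (0 = z, 1 = y, 2 = x),
// edge-clamped boundaries. Kernel must have odd length.
static void conv_axis(const std::vector<double> &in, std::vector<double> &out,
                      int nz, int ny, int nx, const NumericVector &k, int axis) {
  int kl = k.size(), half = kl / 2;
  int n[3] = {nz, ny, nx};
  int len = n[axis];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int c[3] = {z, y, x};
        double acc = 0.0;
        for (int j = 0; j < kl; ++j) {
          int p = c[axis] + j - half;
          if (p < 0) p = 0;
          if (p >= len) p = len - 1;
          int cc[3] = {z, y, x};
          cc[axis] = p;
          acc += k[j] * in[IDX(cc[0], cc[1], cc[2], nz, ny)];
        }
        out[IDX(z, y, x, nz, ny)] = acc;
      }
}

// [[Rcpp::export]]
NumericVector cpp_sep_conv3(NumericVector vol, IntegerVector dim, List kernels) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  for (int axis = 0; axis < 3; ++axis) {
    NumericVector k = kernels[axis];
    if (k.size() <= 1) continue;
    conv_axis(a, b, nz, ny, nx, k, axis);
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Running min or max with half-width r along one axis.
static void minmax_axis(const std::vector<double> &in, std::vector<double> &out,
                        int nz, int ny, int nx, int r, int axis, bool do_min) {
  int n[3] = {nz, ny, nx};
  int len = n[axis];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int c[3] = {z, y, x};
        int lo = std::max(0, c[axis] - r), hi = std::min(len - 1, c[axis] + r);
        double best = do_min ? std::numeric_limits<double>::infinity()
                             : -std::numeric_limits<double>::infinity();
        for (int p = lo; p <= hi; ++p) {
          int cc[3] = {z, y, x};
          cc[axis] = p;
          double v = in[IDX(cc[0], cc[1], cc[2], nz, ny)];
          if (do_min ? (v < best) : (v > best)) best = v;
        }
        out[IDX(z, y, x, nz, ny)] = best;
      }
}

// Greyscale erosion (do_min) or dilation with a box of per-axis half-widths.
// [[Rcpp::export]]
NumericVector cpp_box_filter3(NumericVector vol, IntegerVector dim,
                              IntegerVector radius, bool do_min) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  for (int axis = 0; axis < 3; ++axis) {
    if (radius[axis] <= 0) continue;
    minmax_axis(a, b, nz, ny, nx, radius[axis], axis, do_min);
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling of a logical mask. Labels 1..N in
// first-encounter (linear index) order.
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    lab[i] = ++next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur % nz);
      int rem = (int)(cur / nz);
      int y = rem % ny, x = rem / ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = IDX(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_labels") = next;
  return lab;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
static void edt1d(std::vector<double> &f, std::vector<double> &d, double step) {
  int n = f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * step, vv = (double)v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * step;
    while (zb[k + 1] < qq) ++k;
    double vv = (double)v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform: distance (um) from each
// foreground voxel to the nearest background voxel. spacing = (z,y,x) um.
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = 1e30;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  int dims[3] = {nz, ny, nx};
  for (int axis = 0; axis < 3; ++axis) {
    int len = dims[axis];
    if (len == 1) continue;
    std::vector<double> f(len), out(len);
    int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 1) ? 1 : ((axis == 2) ? 2 : 1);
    // iterate over all lines along `axis`
    for (int x = 0; x < ((axis == 2) ? 1 : nx); ++x)
      for (int y = 0; y < ((axis == 1) ? 1 : ny); ++y)
        for (int z = 0; z < ((axis == 0) ? 1 : nz); ++z) {
          for (int p = 0; p < len; ++p) {
            int c[3] = {z, y, x};
            c[axis] = p;
            f[p] = d[IDX(c[0], c[1], c[2], nz, ny)];
          }
          edt1d(f, out, spacing[axis]);
          for (int p = 0; p < len; ++p) {
            int c[3] = {z, y, x};
            c[axis] = p;
            d[IDX(c[0], c[1], c[2], nz, ny)] = out[p];
          }
        }
    (void)o1; (void)o2;
  }
  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i) res[i] = std::sqrt(d[i]);
  res.attr("dim") = dim;
  return res;
}

// Local maxima of `vol` within `mask` under 26-connectivity (plateaus count).
// [[Rcpp::export]]
LogicalVector cpp_local_maxima3(NumericVector vol, IntegerVector dim, LogicalVector mask) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n, false);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = IDX(z, y, x, nz, ny);
        if (!mask[i]) continue;
        double v = vol[i];
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (!dz && !dy && !dx) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                continue;
              if (vol[IDX(zz, yy, xx, nz, ny)] > v) ismax = false;
            }
        out[i] = ismax;
      }
  out.attr("dim") = dim;
  return out;
}

struct WsNode {
  double prio;
  long long order;
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.prio != b.prio) return a.prio < b.prio; // higher priority first
    return a.order > b.order;                     // then FIFO (stable)
  }
};

// Seeded watershed by priority flooding: voxels with higher `prio` are
// claimed first; seeds carry labels; growth restricted to mask.
// [[Rcpp::export]]
IntegerVector cpp_watershed3(NumericVector prio, IntegerVector seeds,
                             LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long order = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push({prio[i], order++, i});
    }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    R_xlen_t cur = nd.idx;
    int z = (int)(cur % nz);
    int rem = (int)(cur / nz);
    int y = rem % ny, x = rem / ny;
    int l = lab[cur];
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          R_xlen_t j = IDX(zz, yy, xx, nz, ny);
          if (mask[j] && lab[j] == 0) {
            lab[j] = l;
            pq.push({prio[j], order++, j});
          }
        }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Exhaustive minimum Euclidean distance from each query point to a
// reference point set (both k x 3, in um). Returns distances and 1-based
// index of the nearest reference point.
// [[Rcpp::export]]
List cpp_min_dist(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  NumericVector dist(nq);
  IntegerVector nearest(nq);
  for (int i = 0; i < nq; ++i) {
    double q0 = query(i, 0), q1 = query(i, 1), q2 = query(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    for (int j = 0; j < nr; ++j) {
      double d0 = ref(j, 0) - q0, d1 = ref(j, 1) - q1, d2 = ref(j, 2) - q2;
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) { best = d; bj = j; }
    }
    dist[i] = std::sqrt(best);
    nearest[i] = bj + 1;
  }
  return List::create(_["dist_um"] = dist, _["nearest"] = nearest);
}
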