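#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// ---- exact squared Euclidean distance transform -------------------------
// Felzenszwalb & Huttenlocher lower-envelope algorithm, one 1D pass per
// axis. Sample positions along an axis are i * h where h is the physical
// spacing for that axis, so anisotropic voxels are handled exactly.

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 double h, std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { // no sites on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue; // infinite parabolas never enter the envelope
    double s;
    for (;;) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared EDT of the complement of `mask`: for every voxel, squared
// physical distance (spacing in `spacing`, per axis, same order as `dim`)
// to the nearest TRUE voxel. TRUE voxels get 0. All-FALSE masks give Inf.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nd = dim.size();
  if (nd < 1 || nd > 3) stop("dim must have 1-3 entries");
  if (spacing.size() != nd) stop("spacing length must match dim");
  R_xlen_t total = 1;
  for (int a = 0; a < nd; ++a) {
    if (dim[a] < 1) stop("dims must be positive");
    if (!(spacing[a] > 0)) stop("spacing must be > 0");
    total *= dim[a];
  }
  if (mask.size() != total) stop("mask length does not match dim");

  NumericVector out(total);
  for (R_xlen_t i = 0; i < total; ++i)
    out[i] = mask[i] ? 0.0 : INF;

  int nmax = 0;
  for (int a = 0; a < nd; ++a) if (dim[a] > nmax) nmax = dim[a];
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // column-major strides
  std::vector<R_xlen_t> stride(nd);
  stride[0] = 1;
  for (int a = 1; a < nd; ++a) stride[a] = stride[a - 1] * dim[a - 1];

  for (int a = 0; a < nd; ++a) {
    int n = dim[a];
    R_xlen_t sa = stride[a];
    R_xlen_t nlines = total / n;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // base index of this line: distribute `line` over the other axes
      R_xlen_t rem = line, base = 0;
      for (int b = 0; b < nd; ++b) {
        if (b == a) continue;
        R_xlen_t idx = rem % dim[b];
        rem /= dim[b];
        base += idx * stride[b];
      }
      bool any = false;
      for (int q = 0; q < n; ++q) {
        f[q] = out[base + q * sa];
        if (f[q] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, d, n, spacing[a], v, z);
      for (int q = 0; q < n; ++q) out[base + q * sa] = d[q];
    }
  }
  return out;
}

// ---- connected components ----------------------------------------------
// Flood-fill labeling: 8-connectivity in 2D, 26-connectivity in 3D.
// Labels are assigned in ascending linear (column-major raster) order of
// each component's first voxel, so labeling is deterministic.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  int nd = dim.size();
  if (nd < 2 || nd > 3) stop("dim must have 2 or 3 entries");
  R_xlen_t total = 1;
  for (int a = 0; a < nd; ++a) total *= dim[a];
  if (mask.size() != total) stop("mask length does not match dim");

  int d1 = dim[0], d2 = dim[1], d3 = (nd == 3) ? dim[2] : 1;
  IntegerVector lab(total, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;

  for (R_xlen_t start = 0; start < total; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int i1 = (int)(cur % d1);
      int i2 = (int)((cur / d1) % d2);
      int i3 = (int)(cur / ((R_xlen_t)d1 * d2));
      int lo3 = (nd == 3) ? -1 : 0, hi3 = (nd == 3) ? 1 : 0;
      for (int o3 = lo3; o3 <= hi3; ++o3) {
        int j3 = i3 + o3;
        if (j3 < 0 || j3 >= d3) continue;
        for (int o2 = -1; o2 <= 1; ++o2) {
          int j2 = i2 + o2;
          if (j2 < 0 || j2 >= d2) continue;
          for (int o1 = -1; o1 <= 1; ++o1) {
            int j1 = i1 + o1;
            if (j1 < 0 || j1 >= d1) continue;
            R_xlen_t nb = j1 + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * j3);
            if (nb == cur || !mask[nb] || lab[nb] != 0) continue;
            lab[nb] = next;
            queue.push_back(nb);
          }
        }
      }
    }
  }
  return lab;
}
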