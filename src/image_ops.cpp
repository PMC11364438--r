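#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 3-D connected-component labelling on a logical volume.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns integer labels (0 = background) in the same linear layout.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim,
                          int connectivity = 26) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);

  // neighbour offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int nnb = (int)ox.size();

  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nnb; ++k) {
        int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

static void blur_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, const std::vector<double>& kernel) {
  const int r = (int)(kernel.size() / 2);
  const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  if (len == 1 || r == 0) return;
  std::vector<double> line(len), out(len);
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nx : (R_xlen_t)nx * ny;
  // iterate over all lines along `axis`
  int n1 = (axis == 0) ? ny : nx;
  int n2 = (axis == 2) ? ny : nz;
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      R_xlen_t base;
      if (axis == 0)      base = (R_xlen_t)j2 * nx * ny + (R_xlen_t)j1 * nx;
      else if (axis == 1) base = (R_xlen_t)j2 * nx * ny + j1;
      else                base = (R_xlen_t)j2 * nx + j1;
      for (int i = 0; i < len; ++i) line[i] = a[base + stride * i];
      for (int i = 0; i < len; ++i) {
        double s = 0.0;
        for (int k = -r; k <= r; ++k) {
          int idx = i + k;
          if (idx < 0) idx = -idx - 1;            // reflect
          if (idx >= len) idx = 2 * len - idx - 1;
          s += kernel[k + r] * line[idx];
        }
        out[i] = s;
      }
      for (int i = 0; i < len; ++i) a[base + stride * i] = out[i];
    }
  }
}

// Separable Gaussian blur of a 3-D volume, reflect padding, kernel
// truncated at 3 sigma. sigma in voxels (scalar, isotropic).
// [[Rcpp::export(name = ".gauss_blur_3d")]]
NumericVector gauss_blur_3d(NumericVector arr, IntegerVector dim,
                            double sigma) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (arr.size() != n) stop("array length does not match dim");
  if (sigma <= 0) return clone(arr);

  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> kernel(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; ++k) {
    kernel[k + r] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
    s += kernel[k + r];
  }
  for (double& v : kernel) v /= s;

  std::vector<double> a(arr.begin(), arr.end());
  blur_axis(a, nx, ny, nz, 0, kernel);
  blur_axis(a, nx, ny, nz, 1, kernel);
  blur_axis(a, nx, ny, nz, 2, kernel);
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Binary dilation by a 3x3x3 box repeated `iter` times (separable running
// max along each axis).
// [[Rcpp::export(name = ".box_dilate_3d")]]
LogicalVector box_dilate_3d(LogicalVector mask, IntegerVector dim,
                            int iter = 1) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<char> a(mask.begin(), mask.end()), b(n);
  for (int it = 0; it < iter; ++it) {
    for (int axis = 0; axis < 3; ++axis) {
      R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nx : (R_xlen_t)nx * ny;
      int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
      int n1 = (axis == 0) ? ny : nx;
      int n2 = (axis == 2) ? ny : nz;
      for (int j2 = 0; j2 < n2; ++j2) {
        for (int j1 = 0; j1 < n1; ++j1) {
          R_xlen_t base;
          if (axis == 0)      base = (R_xlen_t)j2 * nx * ny + (R_xlen_t)j1 * nx;
          else if (axis == 1) base = (R_xlen_t)j2 * nx * ny + j1;
          else                base = (R_xlen_t)j2 * nx + j1;
          for (int i = 0; i < len; ++i) {
            char v = a[base + stride * i];
            if (!v && i > 0) v = a[base + stride * (i - 1)];
            if (!v && i + 1 < len) v = a[base + stride * (i + 1)];
            b[base + stride * i] = v;
          }
        }
      }
      std::swap(a, b);
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (int)a[i];
  out.attr("dim") = dim;
  return out;
}

// Constrained label dilation: for `iter` passes, every unlabelled voxel of
// `mask` adjacent (26-connectivity) to a labelled voxel takes the smallest
// positive neighbouring label. Used to grow eroded component cores back to
// their full extent without absorbing thin unconnected films.
// [[Rcpp::export(name = ".label_dilate_3d")]]
IntegerVector label_dilate_3d(IntegerVector labels, LogicalVector mask,
                              IntegerVector dim, int iter = 1) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (labels.size() != n || mask.size() != n) stop("length mismatch");
  std::vector<int> cur(labels.begin(), labels.end()), nxt;
  for (int it = 0; it < iter; ++it) {
    nxt = cur;
    for (R_xlen_t v = 0; v < n; ++v) {
      if (!mask[v] || cur[v] != 0) continue;
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      int best = 0;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            int lv = cur[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
            if (lv > 0 && (best == 0 || lv < best)) best = lv;
          }
      if (best > 0) nxt[v] = best;
    }
    std::swap(cur, nxt);
  }
  IntegerVector out(n);
  std::copy(cur.begin(), cur.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Binary erosion by a 3x3x3 box repeated `iter` times (separable running
// min along each axis; voxels outside the volume count as background, so
// foreground touching the border erodes like any other boundary).
// [[Rcpp::export(name = ".box_erode_3d")]]
LogicalVector box_erode_3d(LogicalVector mask, IntegerVector dim,
                           int iter = 1) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<char> a(mask.begin(), mask.end()), b(n);
  for (int it = 0; it < iter; ++it) {
    for (int axis = 0; axis < 3; ++axis) {
      R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nx : (R_xlen_t)nx * ny;
      int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
      int n1 = (axis == 0) ? ny : nx;
      int n2 = (axis == 2) ? ny : nz;
      for (int j2 = 0; j2 < n2; ++j2) {
        for (int j1 = 0; j1 < n1; ++j1) {
          R_xlen_t base;
          if (axis == 0)      base = (R_xlen_t)j2 * nx * ny + (R_xlen_t)j1 * nx;
          else if (axis == 1) base = (R_xlen_t)j2 * nx * ny + j1;
          else                base = (R_xlen_t)j2 * nx + j1;
          for (int i = 0; i < len; ++i) {
            char v = a[base + stride * i];
            if (v && i > 0) v = a[base + stride * (i - 1)];
            else if (v && i == 0) v = 0;
            if (v && i + 1 < len) v = a[base + stride * (i + 1)];
            else if (v && i + 1 == len) v = 0;
            b[base + stride * i] = v;
          }
        }
      }
      std::swap(a, b);
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (int)a[i];
  out.attr("dim") = dim;
  return out;
}
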