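#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Running temporal median per pixel over a frame stack.
//
// stack is a ny x nx x nt numeric array; window must be odd and >= 3.
// The window is truncated (shrinks) at the stack ends, so frames near the
// edges use whatever frames exist within +/- (window-1)/2.  The median of an
// even-sized truncated window is the mean of the two middle order statistics
// (matching stats::median), so the output is bit-comparable to a brute-force
// per-pixel sliding median.
// [[Rcpp::export]]
NumericVector cpp_temporal_median(NumericVector stack, int window) {
  IntegerVector dim = stack.attr("dim");
  if (dim.size() != 3) stop("stack must be a 3D array (ny, nx, nt)");
  const int ny = dim[0], nx = dim[1], nt = dim[2];
  if (window % 2 == 0 || window < 3)
    stop("window must be odd and >= 3");
  if (window > nt)
    stop("window (%d) longer than stack (%d frames)", window, nt);
  const int h = (window - 1) / 2;
  const R_xlen_t fstride = (R_xlen_t)ny * nx;

  NumericVector out(stack.size());
  out.attr("dim") = dim;

  std::vector<double> win;      // sorted sliding window
  win.reserve(window);

  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      const R_xlen_t base = iy + (R_xlen_t)ny * ix;
      win.clear();
      // initial window for t = 0: frames [0, h]
      for (int t = 0; t <= h && t < nt; ++t) {
        double v = stack[base + fstride * t];
        win.insert(std::lower_bound(win.begin(), win.end(), v), v);
      }
      int lo = 0, hi = std::min(h, nt - 1);
      for (int t = 0; t < nt; ++t) {
        if (t > 0) {
          int nlo = std::max(0, t - h);
          int nhi = std::min(nt - 1, t + h);
          if (nhi > hi) {
            double v = stack[base + fstride * nhi];
            win.insert(std::lower_bound(win.begin(), win.end(), v), v);
            hi = nhi;
          }
          if (nlo > lo) {
            double v = stack[base + fstride * lo];
            win.erase(std::lower_bound(win.begin(), win.end(), v));
            lo = nlo;
          }
        }
        const size_t m = win.size();
        double med;
        if (m % 2 == 1) med = win[m / 2];
        else med = 0.5 * (win[m / 2 - 1] + win[m / 2]);
        out[base + fstride * t] = med;
      }
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask.
// Returns an integer matrix: 0 for background, 1..k component ids
// (labelled in column-major discovery order).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int next = 0;
  std::vector<std::pair<int, int> > stackpx;
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      if (!mask(iy, ix) || lab(iy, ix) != 0) continue;
      ++next;
      stackpx.clear();
      stackpx.push_back(std::make_pair(iy, ix));
      lab(iy, ix) = next;
      while (!stackpx.empty()) {
        std::pair<int, int> p = stackpx.back();
        stackpx.pop_back();
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dy == 0 && dx == 0) continue;
            int jy = p.first + dy, jx = p.second + dx;
            if (jy < 0 || jy >= ny || jx < 0 || jx >= nx) continue;
            if (mask(jy, jx) && lab(jy, jx) == 0) {
              lab(jy, jx) = next;
              stackpx.push_back(std::make_pair(jy, jx));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Windowed cross-correlation of two sparse 2D histograms.
//
// (xi, yi, wi) and (xj, yj, wj) are the nonzero bins (integer bin indices
// on a common grid) and weights of the two segment images.  Returns the
// (2m+1) x (2m+1) correlation matrix C with
//   C(dy + m, dx + m) = sum over bin pairs q - p = (dx, dy) of w_i(p) w_j(q),
// i.e. the cross-correlation restricted to shifts |dx|,|dy| <= m bins.
// [[Rcpp::export]]
NumericMatrix cpp_sparse_xcorr(IntegerVector xi, IntegerVector yi,
                               NumericVector wi, IntegerVector xj,
                               IntegerVector yj, NumericVector wj, int m) {
  const int ni = xi.size(), nj = xj.size();
  NumericMatrix C(2 * m + 1, 2 * m + 1);
  // sort j bins by x for range pruning
  std::vector<int> ord(nj);
  for (int k = 0; k < nj; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return xj[a] < xj[b]; });
  std::vector<int> xs(nj);
  for (int k = 0; k < nj; ++k) xs[k] = xj[ord[k]];
  for (int a = 0; a < ni; ++a) {
    const int x0 = xi[a], y0 = yi[a];
    const double w0 = wi[a];
    int lo = std::lower_bound(xs.begin(), xs.end(), x0 - m) - xs.begin();
    int hi = std::upper_bound(xs.begin(), xs.end(), x0 + m) - xs.begin();
    for (int k = lo; k < hi; ++k) {
      const int b = ord[k];
      const int dy = yj[b] - y0;
      if (dy < -m || dy > m) continue;
      const int dx = xj[b] - x0;
      C(dy + m, dx + m) += w0 * wj[b];
    }
  }
  return C;
}
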