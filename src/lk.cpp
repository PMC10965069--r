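#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pyramidal Lucas-Kanade sparse optical flow.
//
// Images are R numeric matrices (rows x cols) with intensities on any
// finite scale. Marker positions are 0-based (row, col) doubles here;
// the R wrapper converts from the package's 1-based convention.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sample with replicate padding at the borders.
static inline double sample_bilinear(const NumericMatrix& img, double r, double c) {
  int nr = img.nrow(), nc = img.ncol();
  r = clampd(r, 0.0, nr - 1.0);
  c = clampd(c, 0.0, nc - 1.0);
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 > nr - 2) r0 = nr - 2;
  if (c0 > nc - 2) c0 = nc - 2;
  if (r0 < 0) r0 = 0;
  if (c0 < 0) c0 = 0;
  double fr = r - r0, fc = c - c0;
  double v00 = img(r0, c0),     v01 = img(r0, c0 + 1);
  double v10 = img(r0 + 1, c0), v11 = img(r0 + 1, c0 + 1);
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
}

// Downsample by 2 with the 5-tap binomial kernel [1 4 6 4 1]/16 (separable),
// replicate border handling; output size ceil(n/2).
// [[Rcpp::export(name = ".pyr_down")]]
NumericMatrix pyr_down(const NumericMatrix& img) {
  int nr = img.nrow(), nc = img.ncol();
  int mr = (nr + 1) / 2, mc = (nc + 1) / 2;
  static const double k[5] = {1.0/16, 4.0/16, 6.0/16, 4.0/16, 1.0/16};
  NumericMatrix tmp(nr, mc), out(mr, mc);
  for (int j = 0; j < mc; ++j) {
    int cj = 2 * j;
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -2; t <= 2; ++t) {
        int cc = cj + t;
        if (cc < 0) cc = 0; else if (cc > nc - 1) cc = nc - 1;
        acc += k[t + 2] * img(i, cc);
      }
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < mc; ++j) {
    for (int i = 0; i < mr; ++i) {
      int ri = 2 * i;
      double acc = 0.0;
      for (int t = -2; t <= 2; ++t) {
        int rr = ri + t;
        if (rr < 0) rr = 0; else if (rr > nr - 1) rr = nr - 1;
        acc += k[t + 2] * tmp(rr, j);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Levels beyond which the image gets smaller than 8 px a side are dropped,
// so the returned list may be shorter than requested.
// [[Rcpp::export(name = ".build_pyramid")]]
List build_pyramid(const NumericMatrix& img, int levels) {
  List pyr;
  pyr.push_back(img);
  NumericMatrix cur = img;
  for (int l = 1; l < levels; ++l) {
    if (cur.nrow() < 16 || cur.ncol() < 16) break;
    cur = pyr_down(cur);
    pyr.push_back(cur);
  }
  return pyr;
}

// Track markers from prev to next. pts: M x 2 (row, col), 0-based.
// Returns list(pts = M x 2 new positions, status = logical M).
// [[Rcpp::export(name = ".lk_step")]]
List lk_step(const List& prev_pyr, const List& next_pyr, const NumericMatrix& pts,
             int win, int max_iter, double eps, double min_eig) {
  int levels = prev_pyr.size();
  int M = pts.nrow();
  int hw = (win - 1) / 2;
  NumericMatrix out(M, 2);
  LogicalVector status(M);
  int wpad = win + 2; // template patch with 1-px rim for gradients

  std::vector<double> patch(wpad * wpad), ix(win * win), iy(win * win), tmpl(win * win);

  for (int m = 0; m < M; ++m) {
    double gr = 0.0, gc = 0.0;      // flow propagated from coarser levels
    bool ok = true;
    double pr_top = pts(m, 0), pc_top = pts(m, 1);
    for (int l = levels - 1; l >= 0; --l) {
      NumericMatrix I = prev_pyr[l];
      NumericMatrix J = next_pyr[l];
      double scale = std::pow(2.0, l);
      double pr = pr_top / scale, pc = pc_top / scale;
      int nr = I.nrow(), nc = I.ncol();
      // template window must fit (with gradient rim) inside prev level
      if (pr - hw - 1 < 0 || pr + hw + 1 > nr - 1 ||
          pc - hw - 1 < 0 || pc + hw + 1 > nc - 1) {
        if (l == 0) ok = false; // unusable at full resolution
        // at coarse levels just skip refinement
        gr *= 2.0; gc *= 2.0;
        continue;
      }
      // sample template patch and gradients from I
      for (int a = 0; a < wpad; ++a)
        for (int b = 0; b < wpad; ++b)
          patch[a * wpad + b] = sample_bilinear(I, pr + a - hw - 1, pc + b - hw - 1);
      double g11 = 0, g12 = 0, g22 = 0;
      for (int a = 0; a < win; ++a) {
        for (int b = 0; b < win; ++b) {
          int pa = a + 1, pb = b + 1;
          double dr = 0.5 * (patch[(pa + 1) * wpad + pb] - patch[(pa - 1) * wpad + pb]);
          double dc = 0.5 * (patch[pa * wpad + pb + 1] - patch[pa * wpad + pb - 1]);
          int idx = a * win + b;
          ix[idx] = dr; iy[idx] = dc; tmpl[idx] = patch[pa * wpad + pb];
          g11 += dr * dr; g12 += dr * dc; g22 += dc * dc;
        }
      }
      double tr = g11 + g22;
      double det = g11 * g22 - g12 * g12;
      double lmin = 0.5 * (tr - std::sqrt(std::max(0.0, tr * tr - 4.0 * det)));
      if (lmin / (win * win) < min_eig || det <= 0) {
        if (l == 0) ok = false;
        gr *= 2.0; gc *= 2.0;
        continue;
      }
      double vr = 0.0, vc = 0.0;
      for (int it = 0; it < max_iter; ++it) {
        double qr = pr + gr + vr, qc = pc + gc + vc;
        if (qr - hw < 0 || qr + hw > J.nrow() - 1 || qc - hw < 0 || qc + hw > J.ncol() - 1) {
          if (l == 0) ok = false;
          break;
        }
        double br = 0.0, bc = 0.0;
        for (int a = 0; a < win; ++a) {
          for (int b = 0; b < win; ++b) {
            double diff = tmpl[a * win + b] - sample_bilinear(J, qr + a - hw, qc + b - hw);
            br += diff * ix[a * win + b];
            bc += diff * iy[a * win + b];
          }
        }
        double dvr = (g22 * br - g12 * bc) / det;
        double dvc = (-g12 * br + g11 * bc) / det;
        vr += dvr; vc += dvc;
        if (std::sqrt(dvr * dvr + dvc * dvc) < eps) break;
        if (std::sqrt(vr * vr + vc * vc) > 2.0 * win) break; // diverged
      }
      // a win-sized window cannot validly measure motion beyond its own
      // support: discard oversized flow at coarse levels, fail at level 0
      if (std::sqrt(vr * vr + vc * vc) > win) {
        if (l == 0) ok = false; else { vr = 0.0; vc = 0.0; }
      }
      gr = 2.0 * (gr + vr);
      gc = 2.0 * (gc + vc);
      if (!ok) break;
    }
    if (ok) {
      double nr0 = pr_top + gr / 2.0, nc0 = pc_top + gc / 2.0; // undo last doubling
      NumericMatrix J0 = next_pyr[0];
      if (!std::isfinite(nr0) || !std::isfinite(nc0) ||
          nr0 < 0 || nr0 > J0.nrow() - 1 || nc0 < 0 || nc0 > J0.ncol() - 1)
        ok = false;
      out(m, 0) = nr0; out(m, 1) = nc0;
    }
    if (!ok) { out(m, 0) = pts(m, 0); out(m, 1) = pts(m, 1); }
    status[m] = ok;
  }
  return List::create(Named("pts") = out, Named("status") = status);
}
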