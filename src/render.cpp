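#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Accumulate anisotropic Gaussian-profiled ellipse kernels into an image.
// Kernels are truncated at two long-axis sigmas. Coordinates are 1-based
// (row, col) matching R matrices.
// [[Rcpp::export]]
NumericMatrix render_kernels_cpp(NumericMatrix img, NumericVector rows,
                                 NumericVector cols, NumericVector amps,
                                 double sigma_l, double sigma_s,
                                 NumericVector angles) {
  int H = img.nrow(), W = img.ncol(), n = rows.size();
  double cut2 = 4.0 * sigma_l * sigma_l;
  int h = (int)std::ceil(2.0 * sigma_l);
  for (int i = 0; i < n; ++i) {
    double r = rows[i], c = cols[i], A = amps[i];
    double ca = std::cos(angles[i]), sa = std::sin(angles[i]);
    int r0 = std::max(1, (int)std::floor(r - h));
    int r1 = std::min(H, (int)std::ceil(r + h));
    int c0 = std::max(1, (int)std::floor(c - h));
    int c1 = std::min(W, (int)std::ceil(c + h));
    for (int cc = c0; cc <= c1; ++cc) {
      double dx = cc - c;
      for (int rr = r0; rr <= r1; ++rr) {
        double dy = rr - r;
        if (dx * dx + dy * dy > cut2) continue;
        double u = dx * ca + dy * sa;
        double v = -dx * sa + dy * ca;
        img(rr - 1, cc - 1) +=
            A * std::exp(-u * u / (2 * sigma_l * sigma_l) -
                         v * v / (2 * sigma_s * sigma_s));
      }
    }
  }
  return img;
}

// Accumulate flat discs (spores) into an image.
// [[Rcpp::export]]
NumericMatrix render_discs_cpp(NumericMatrix img, NumericVector rows,
                               NumericVector cols, NumericVector amps,
                               double radius) {
  int H = img.nrow(), W = img.ncol(), n = rows.size();
  int h = (int)std::ceil(radius) + 1;
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    double r = rows[i], c = cols[i], A = amps[i];
    int r0 = std::max(1, (int)std::floor(r - h));
    int r1 = std::min(H, (int)std::ceil(r + h));
    int c0 = std::max(1, (int)std::floor(c - h));
    int c1 = std::min(W, (int)std::ceil(c + h));
    for (int cc = c0; cc <= c1; ++cc) {
      double dx = cc - c;
      for (int rr = r0; rr <= r1; ++rr) {
        double dy = rr - r;
        if (dx * dx + dy * dy <= r2) img(rr - 1, cc - 1) += A;
      }
    }
  }
  return img;
}

// Exact Euclidean distance (px) from points to the sampled top-boundary
// polyline (one boundary point per image column).
// [[Rcpp::export]]
NumericVector boundary_depth_cpp(NumericVector rows, NumericVector cols,
                                 NumericVector top_px) {
  int n = rows.size(), W = top_px.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int c = 0; c < W; ++c) {
      double dr = rows[i] - top_px[c];
      double dc = cols[i] - (c + 1);
      double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
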