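#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling of a binary image by flood fill.
// connectivity must be 4 or 8. Labels are 1..k in scan order, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(const LogicalMatrix& mask, int connectivity) {
  const int m = mask.nrow(), n = mask.ncol();
  IntegerMatrix lab(m, n);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  const int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < n; ++c) {
    for (int r = 0; r < m; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * m);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % m, cc = idx / m;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= m || c2 < 0 || c2 >= n) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * m);
          }
        }
      }
    }
  }
  return lab;
}

// Brute-force bilateral filter with a Gaussian spatial kernel truncated at
// 2*sigma_s and a Gaussian range kernel. Borders use the available window.
// [[Rcpp::export]]
NumericMatrix bilateral_cpp(const NumericMatrix& img, double sigma_s, double sigma_r) {
  const int m = img.nrow(), n = img.ncol();
  const int rad = std::max(1, (int)std::ceil(2.0 * sigma_s));
  const double ss2 = 2.0 * sigma_s * sigma_s;
  const double sr2 = 2.0 * sigma_r * sigma_r;
  const int w = 2 * rad + 1;
  std::vector<double> spat(w * w);
  for (int di = -rad; di <= rad; ++di)
    for (int dj = -rad; dj <= rad; ++dj)
      spat[(di + rad) + (dj + rad) * w] = std::exp(-(double)(di * di + dj * dj) / ss2);
  NumericMatrix out(m, n);
  for (int c = 0; c < n; ++c) {
    for (int r = 0; r < m; ++r) {
      const double v0 = img(r, c);
      double acc = 0.0, wsum = 0.0;
      const int r1 = std::max(0, r - rad), r2 = std::min(m - 1, r + rad);
      const int c1 = std::max(0, c - rad), c2 = std::min(n - 1, c + rad);
      for (int cc = c1; cc <= c2; ++cc) {
        for (int rr = r1; rr <= r2; ++rr) {
          const double dv = img(rr, cc) - v0;
          const double wgt = spat[(rr - r + rad) + (cc - c + rad) * w] *
            std::exp(-dv * dv / sr2);
          acc += wgt * img(rr, cc);
          wsum += wgt;
        }
      }
      out(r, c) = acc / wsum;
    }
  }
  return out;
}
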