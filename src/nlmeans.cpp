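#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Non-local means on one channel, offset-wise with integral images:
// for each candidate offset t in the search window, the per-pixel patch SSD
// against the t-shifted image is a box sum of the squared-difference image,
// computed in O(HW) via a summed-area table restricted to the overlap
// region. Patch windows are clamped at borders and normalized by the actual
// pixel count; weights below exp(-30) are skipped.
// [[Rcpp::export]]
NumericMatrix nlmeans_channel(NumericMatrix img, double h, int patch, int win) {
  const int H = img.nrow(), W = img.ncol();
  const int pr = patch / 2, wr = win / 2;
  const double h2 = h * h;
  const double* x = img.begin();            // column-major, H rows

  NumericMatrix num(H, W), den(H, W);
  double* pnum = num.begin();
  double* pden = den.begin();
  std::vector<double> sat;

  for (int dy = -wr; dy <= wr; ++dy) {      // column offset
    for (int dx = -wr; dx <= wr; ++dx) {    // row offset
      const int i0 = std::max(0, -dx), i1 = std::min(H, H - dx);
      const int j0 = std::max(0, -dy), j1 = std::min(W, W - dy);
      const int nr = i1 - i0, nc = j1 - j0;
      if (nr <= 0 || nc <= 0) continue;

      // SAT of squared differences over the overlap, local coords,
      // sat has (nr+1) x (nc+1) entries, row-major local layout
      const int SW = nr + 1;
      sat.assign((size_t)SW * (nc + 1), 0.0);
      for (int j = 0; j < nc; ++j) {
        const double* colA = x + (size_t)(j0 + j) * H;
        const double* colB = x + (size_t)(j0 + j + dy) * H + dx;
        double csum = 0.0;
        double* s0 = &sat[(size_t)j * SW];
        double* s1 = &sat[(size_t)(j + 1) * SW];
        s1[0] = 0.0;
        for (int i = 0; i < nr; ++i) {
          const double v = colA[i0 + i] - colB[i0 + i];
          csum += v * v;
          s1[i + 1] = s0[i + 1] + csum;
        }
      }

      for (int j = j0; j < j1; ++j) {
        const int ca = std::max(j0, j - pr) - j0,
                  cb = std::min(j1 - 1, j + pr) - j0;
        const double* shifted = x + (size_t)(j + dy) * H + dx;
        double* cnum = pnum + (size_t)j * H;
        double* cden = pden + (size_t)j * H;
        for (int i = i0; i < i1; ++i) {
          const int ra = std::max(i0, i - pr) - i0,
                    rb = std::min(i1 - 1, i + pr) - i0;
          const double ssd =
            sat[(size_t)(cb + 1) * SW + (rb + 1)] -
            sat[(size_t)ca * SW + (rb + 1)] -
            sat[(size_t)(cb + 1) * SW + ra] +
            sat[(size_t)ca * SW + ra];
          const int cnt = (rb - ra + 1) * (cb - ca + 1);
          const double a = (ssd / cnt) / h2;
          if (a > 30.0) continue;
          const double w = std::exp(-a);
          cnum[i] += w * shifted[i];
          cden[i] += w;
        }
      }
    }
  }

  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = den(i, j) > 0.0 ? num(i, j) / den(i, j) : img(i, j);
  return out;
}
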