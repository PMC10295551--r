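#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Non-local means denoising of a colour image.
//
// img is an H x W x 3 array (column-major, values 0..255). For every pixel p
// the output is a weighted average over pixels q in a (sw x sw) search window
// centred on p, with weight exp(-d2(p,q)/h^2) where d2 is the mean squared
// intensity difference between the (tw x tw) patches around p and q, averaged
// over the three channels. Windows are clipped at the borders; the patch
// distance is normalised by the number of valid overlapping patch pixels.
//
// Implemented per search offset with an integral image over the squared
// difference plane, so the cost is O(H * W * sw^2) independent of tw.
// [[Rcpp::export]]
NumericVector nlm_denoise_cpp(NumericVector img, int H, int W,
                              int tw, int sw, double h) {
  const int tr = (tw - 1) / 2;
  const int sr = (sw - 1) / 2;
  const double h2 = h * h;
  const int n = H * W;
  const double *I = img.begin();

  std::vector<double> wsum(n, 0.0);
  std::vector<double> acc(3 * (size_t)n, 0.0);
  // integral images, (H+1) x (W+1)
  const int HI = H + 1;
  std::vector<double> SD((size_t)HI * (W + 1));
  std::vector<double> SV((size_t)HI * (W + 1));

  for (int dx = -sr; dx <= sr; ++dx) {
    for (int dy = -sr; dy <= sr; ++dy) {
      // squared channel difference between I(p) and I(p + (dy,dx)),
      // accumulated directly into the integral images; invalid q -> 0 with
      // validity count 0
      for (int x = 0; x <= W; ++x) {
        SD[(size_t)0 + (size_t)HI * x] = 0.0;
        SV[(size_t)0 + (size_t)HI * x] = 0.0;
      }
      for (int y = 0; y <= H; ++y) {
        SD[(size_t)y] = 0.0;
        SV[(size_t)y] = 0.0;
      }
      for (int x = 1; x <= W; ++x) {
        const int qx = (x - 1) + dx;
        const bool colok = qx >= 0 && qx < W;
        for (int y = 1; y <= H; ++y) {
          const int qy = (y - 1) + dy;
          double d = 0.0, v = 0.0;
          if (colok && qy >= 0 && qy < H) {
            const size_t p = (size_t)(y - 1) + (size_t)H * (x - 1);
            const size_t q = (size_t)qy + (size_t)H * qx;
            for (int c = 0; c < 3; ++c) {
              const double diff = I[p + (size_t)c * n] - I[q + (size_t)c * n];
              d += diff * diff;
            }
            v = 1.0;
          }
          const size_t i00 = (size_t)y + (size_t)HI * x;
          const size_t i01 = (size_t)y + (size_t)HI * (x - 1);
          const size_t i10 = (size_t)(y - 1) + (size_t)HI * x;
          const size_t i11 = (size_t)(y - 1) + (size_t)HI * (x - 1);
          SD[i00] = d + SD[i01] + SD[i10] - SD[i11];
          SV[i00] = v + SV[i01] + SV[i10] - SV[i11];
        }
      }
      // patch-averaged distance and weight accumulation
      for (int x = 0; x < W; ++x) {
        const int qx = x + dx;
        if (qx < 0 || qx >= W) continue;
        const int x0 = std::max(0, x - tr), x1 = std::min(W - 1, x + tr);
        for (int y = 0; y < H; ++y) {
          const int qy = y + dy;
          if (qy < 0 || qy >= H) continue;
          const int y0 = std::max(0, y - tr), y1 = std::min(H - 1, y + tr);
          const size_t a = (size_t)(y1 + 1) + (size_t)HI * (x1 + 1);
          const size_t b = (size_t)(y1 + 1) + (size_t)HI * x0;
          const size_t cidx = (size_t)y0 + (size_t)HI * (x1 + 1);
          const size_t dd = (size_t)y0 + (size_t)HI * x0;
          const double cnt = SV[a] - SV[b] - SV[cidx] + SV[dd];
          if (cnt <= 0) continue;
          const double d2 = (SD[a] - SD[b] - SD[cidx] + SD[dd]) / (3.0 * cnt);
          const double w = std::exp(-d2 / h2);
          const size_t p = (size_t)y + (size_t)H * x;
          const size_t q = (size_t)qy + (size_t)H * qx;
          wsum[p] += w;
          for (int c = 0; c < 3; ++c)
            acc[p + (size_t)c * n] += w * I[q + (size_t)c * n];
        }
      }
    }
  }

  NumericVector out(3 * (size_t)n);
  for (size_t p = 0; p < (size_t)n; ++p)
    for (int c = 0; c < 3; ++c)
      out[p + (size_t)c * n] = acc[p + (size_t)c * n] / wsum[p];
  out.attr("dim") = IntegerVector::create(H, W, 3);
  return out;
}
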