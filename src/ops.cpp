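// Hot loops: depthwise spatial convolution (forward/backward) for the
// ConvNeXt-style regressor, and Catmull-Rom bicubic resampling used to
// downsample Hartmannograms for the network input.
//
// Activation layout convention (shared with the R side): a batch of feature
// maps is a P x C matrix with P = H * W * B rows ordered y-fastest, then x,
// then batch; channels along columns. Depthwise kernels are (k*k) x C with
// rows ordered ky-fastest. Same-size zero padding, stride 1.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix dwconv_forward(const NumericMatrix& X, int H, int W, int B,
                             const NumericMatrix& K, int ksize) {
  const int C = X.ncol();
  const int pad = (ksize - 1) / 2;
  NumericMatrix Y(X.nrow(), C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    const double* kc = &K(0, c);
    double* yc = &Y(0, c);
    for (int b = 0; b < B; ++b) {
      const double* xi = xc + (size_t)b * H * W;
      double* yi = yc + (size_t)b * H * W;
      for (int x = 0; x < W; ++x) {
        for (int y = 0; y < H; ++y) {
          double acc = 0.0;
          for (int kx = 0; kx < ksize; ++kx) {
            int xx = x + kx - pad;
            if (xx < 0 || xx >= W) continue;
            const double* col = xi + (size_t)xx * H;
            const double* krow = kc + (size_t)kx * ksize;
            int y0 = y - pad;
            for (int ky = 0; ky < ksize; ++ky) {
              int yy = y0 + ky;
              if (yy < 0 || yy >= H) continue;
              acc += col[yy] * krow[ky];
            }
          }
          yi[(size_t)x * H + y] = acc;
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List dwconv_backward(const NumericMatrix& X, const NumericMatrix& dY,
                     int H, int W, int B, const NumericMatrix& K, int ksize) {
  const int C = X.ncol();
  const int pad = (ksize - 1) / 2;
  NumericMatrix dX(X.nrow(), C);
  NumericMatrix dK(ksize * ksize, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    const double* gc = &dY(0, c);
    const double* kc = &K(0, c);
    double* dxc = &dX(0, c);
    double* dkc = &dK(0, c);
    for (int b = 0; b < B; ++b) {
      const double* xi = xc + (size_t)b * H * W;
      const double* gi = gc + (size_t)b * H * W;
      double* dxi = dxc + (size_t)b * H * W;
      for (int x = 0; x < W; ++x) {
        for (int y = 0; y < H; ++y) {
          const double g = gi[(size_t)x * H + y];
          if (g == 0.0) continue;
          for (int kx = 0; kx < ksize; ++kx) {
            int xx = x + kx - pad;
            if (xx < 0 || xx >= W) continue;
            double* dxcol = dxi + (size_t)xx * H;
            const double* xcol = xi + (size_t)xx * H;
            const double* krow = kc + (size_t)kx * ksize;
            double* dkrow = dkc + (size_t)kx * ksize;
            int y0 = y - pad;
            for (int ky = 0; ky < ksize; ++ky) {
              int yy = y0 + ky;
              if (yy < 0 || yy >= H) continue;
              dxcol[yy] += g * krow[ky];
              dkrow[ky] += g * xcol[yy];
            }
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dK"] = dK);
}

static inline double cubic_w(double t) {
  // Keys cubic kernel, a = -0.5 (Catmull-Rom)
  const double a = -0.5;
  double at = std::fabs(t);
  if (at <= 1.0) return (a + 2.0) * at * at * at - (a + 3.0) * at * at + 1.0;
  if (at < 2.0)  return a * at * at * at - 5.0 * a * at * at + 8.0 * a * at - 4.0 * a;
  return 0.0;
}

// [[Rcpp::export]]
NumericMatrix bicubic_resize(const NumericMatrix& X, int out_h, int out_w) {
  const int H = X.nrow(), W = X.ncol();
  NumericMatrix Y(out_h, out_w);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  std::vector<double> wy(4), wx(4);
  for (int oc = 0; oc < out_w; ++oc) {
    double xin = (oc + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(xin);
    for (int k = 0; k < 4; ++k) wx[k] = cubic_w(xin - (x0 - 1 + k));
    for (int orow = 0; orow < out_h; ++orow) {
      double yin = (orow + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(yin);
      for (int k = 0; k < 4; ++k) wy[k] = cubic_w(yin - (y0 - 1 + k));
      double acc = 0.0;
      for (int kx = 0; kx < 4; ++kx) {
        int xx = std::min(std::max(x0 - 1 + kx, 0), W - 1);
        double inner = 0.0;
        for (int ky = 0; ky < 4; ++ky) {
          int yy = std::min(std::max(y0 - 1 + ky, 0), H - 1);
          inner += wy[ky] * X(yy, xx);
        }
        acc += wx[kx] * inner;
      }
      Y(orow, oc) = acc;
    }
  }
  return Y;
}
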