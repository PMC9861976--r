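#include <Rcpp.h>
using namespace Rcpp;

// Direct 'same' convolution kernels over (H, W, C) column-major planes.
// Weight layout matches the (k*k*C) x F matrix used by the R model code:
// row index c*k*k + kj*k + ki, with spatial offsets oi = ki - k/2,
// oj = kj - k/2, i.e. y[i, j, f] += w * x[i + oi, j + oj, c].
// The inner loops run down contiguous columns so the compiler can
// vectorize them; planes are small enough to stay cache-resident.

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix W,
                           NumericVector bias, int H, int Wd, int C,
                           int F, int k) {
  int half = k / 2;
  NumericVector y(H * Wd * F);
  double *xp = REAL(x), *yp = REAL(y);
  for (int f = 0; f < F; ++f) {
    double *yf = yp + (size_t)f * H * Wd;
    double b0 = bias[f];
    for (int t = 0; t < H * Wd; ++t) yf[t] = b0;
    for (int c = 0; c < C; ++c) {
      double *xc = xp + (size_t)c * H * Wd;
      for (int kj = 0; kj < k; ++kj) {
        int oj = kj - half;
        for (int ki = 0; ki < k; ++ki) {
          int oi = ki - half;
          double w = W(c * k * k + kj * k + ki, f);
          if (w == 0.0) continue;
          int jlo = std::max(0, -oj), jhi = Wd - 1 - std::max(0, oj);
          int ilo = std::max(0, -oi), ihi = H - 1 - std::max(0, oi);
          for (int j = jlo; j <= jhi; ++j) {
            double *dst = yf + (size_t)j * H;
            double *src = xc + (size_t)(j + oj) * H + oi;
            for (int i = ilo; i <= ihi; ++i) dst[i] += w * src[i];
          }
        }
      }
    }
  }
  return y;
}

// Gradient wrt the input: dx[i+oi, j+oj, c] += w * dz[i, j, f].
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_input(NumericVector dz, NumericMatrix W,
                                 int H, int Wd, int C, int F, int k) {
  int half = k / 2;
  NumericVector dx(H * Wd * C);
  double *zp = REAL(dz), *dp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    double *dc = dp + (size_t)c * H * Wd;
    for (int f = 0; f < F; ++f) {
      double *zf = zp + (size_t)f * H * Wd;
      for (int kj = 0; kj < k; ++kj) {
        int oj = kj - half;
        for (int ki = 0; ki < k; ++ki) {
          int oi = ki - half;
          double w = W(c * k * k + kj * k + ki, f);
          if (w == 0.0) continue;
          int jlo = std::max(0, -oj), jhi = Wd - 1 - std::max(0, oj);
          int ilo = std::max(0, -oi), ihi = H - 1 - std::max(0, oi);
          for (int j = jlo; j <= jhi; ++j) {
            double *src = zf + (size_t)j * H;
            double *dst = dc + (size_t)(j + oj) * H + oi;
            for (int i = ilo; i <= ihi; ++i) dst[i] += w * src[i];
          }
        }
      }
    }
  }
  return dx;
}

// Gradient wrt the weights: dW[(c,kj,ki), f] = sum_ij x[i+oi, j+oj, c] *
// dz[i, j, f]; db[f] = sum_ij dz[i, j, f].
// [[Rcpp::export]]
List cpp_conv_bwd_weights(NumericVector x, NumericVector dz, int H,
                          int Wd, int C, int F, int k) {
  int half = k / 2;
  NumericMatrix dW(k * k * C, F);
  NumericVector db(F);
  double *xp = REAL(x), *zp = REAL(dz);
  for (int f = 0; f < F; ++f) {
    double *zf = zp + (size_t)f * H * Wd;
    double s = 0.0;
    for (int t = 0; t < H * Wd; ++t) s += zf[t];
    db[f] = s;
    for (int c = 0; c < C; ++c) {
      double *xc = xp + (size_t)c * H * Wd;
      for (int kj = 0; kj < k; ++kj) {
        int oj = kj - half;
        for (int ki = 0; ki < k; ++ki) {
          int oi = ki - half;
          int jlo = std::max(0, -oj), jhi = Wd - 1 - std::max(0, oj);
          int ilo = std::max(0, -oi), ihi = H - 1 - std::max(0, oi);
          double acc = 0.0;
          for (int j = jlo; j <= jhi; ++j) {
            double *src = xc + (size_t)(j + oj) * H + oi;
            double *grd = zf + (size_t)j * H;
            for (int i = ilo; i <= ihi; ++i) acc += src[i] * grd[i];
          }
          dW(c * k * k + kj * k + ki, f) = acc;
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}
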