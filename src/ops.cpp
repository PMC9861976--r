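#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 2x2 max pooling; returns pooled values and 1-based argmax indices into x.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, int H, int W, int C) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  double *xo = REAL(x), *o = REAL(out);
  int *ix = INTEGER(idx);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int best = c * H * W + (2 * j) * H + 2 * i;
        double bv = xo[best];
        int cand[3] = {c * H * W + (2 * j) * H + 2 * i + 1,
                       c * H * W + (2 * j + 1) * H + 2 * i,
                       c * H * W + (2 * j + 1) * H + 2 * i + 1};
        for (int t = 0; t < 3; ++t)
          if (xo[cand[t]] > bv) { bv = xo[cand[t]]; best = cand[t]; }
        int oi = c * Ho * Wo + j * Ho + i;
        o[oi] = bv;
        ix[oi] = best + 1;
      }
    }
  }
  return List::create(_["values"] = out, _["argmax"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector argmax,
                                    int H, int W, int C) {
  NumericVector dx(H * W * C);
  double *d = REAL(dx), *g = REAL(dy);
  int *ix = INTEGER(argmax);
  int n = dy.size();
  for (int t = 0; t < n; ++t) d[ix[t] - 1] += g[t];
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, int H, int W, int C) {
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out(Ho * Wo * C);
  double *xo = REAL(x), *o = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        o[c * Ho * Wo + j * Ho + i] = xo[c * H * W + (j / 2) * H + i / 2];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy, int H, int W, int C) {
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(H * W * C);
  double *d = REAL(dx), *g = REAL(dy);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        d[c * H * W + (j / 2) * H + i / 2] += g[c * Ho * Wo + j * Ho + i];
  return dx;
}

// Connected-component labeling of a binary matrix by BFS.
// connectivity is 4 or 8; returns an integer label matrix (0 = background).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix x, int connectivity) {
  int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<int> q;
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      if (!x(i0, j0) || lab(i0, j0)) continue;
      ++next;
      lab(i0, j0) = next;
      q.push(j0 * H + i0);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int i = p % H, j = p / H;
        for (int t = 0; t < nn; ++t) {
          int ni = i + di8[t], nj = j + dj8[t];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (x(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            q.push(nj * H + ni);
          }
        }
      }
    }
  }
  return lab;
}
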