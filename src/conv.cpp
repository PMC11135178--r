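// Hot kernels: 2D convolution forward/backward for the residual denoiser
// and 4-connected component labeling for trace extraction.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// input: (H, W, Cin, N) column-major; weights: (k, k, Cin, Cout); bias: Cout.
// 'same' zero padding, stride 1, square odd kernel.
// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector input, NumericVector weights,
                             NumericVector bias) {
  IntegerVector di = input.attr("dim");
  IntegerVector dw = weights.attr("dim");
  const int H = di[0], W = di[1], Cin = di[2], N = di[3];
  const int k = dw[0], Cout = dw[3];
  const int pad = k / 2;
  NumericVector out((R_xlen_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const double *in = input.begin(), *wt = weights.begin(), *b = bias.begin();
  double *o = out.begin();
  const long sIn_c = (long)H * W, sIn_n = (long)H * W * Cin;
  const long sW_ci = (long)k * k, sW_co = (long)k * k * Cin;
  const long sO_c = (long)H * W, sO_n = (long)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      double *op = o + n * sO_n + co * sO_c;
      for (long i = 0; i < sO_c; ++i) op[i] = b[co];
      for (int ci = 0; ci < Cin; ++ci) {
        const double *ip = in + n * sIn_n + ci * sIn_c;
        const double *wp = wt + co * sW_co + ci * sW_ci;
        for (int kw = 0; kw < k; ++kw) {
          for (int kh = 0; kh < k; ++kh) {
            const double w0 = wp[kh + k * kw];
            if (w0 == 0.0) continue;
            const int dh = kh - pad, dw2 = kw - pad;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const int w0c = std::max(0, -dw2), w1c = std::min(W, W - dw2);
            for (int w2 = w0c; w2 < w1c; ++w2) {
              const double *icol = ip + (long)(w2 + dw2) * H + dh;
              double *ocol = op + (long)w2 * H;
              for (int h = h0; h < h1; ++h) ocol[h] += w0 * icol[h];
            }
          }
        }
      }
    }
  }
  return out;
}

// gradients of the same convolution; returns grad_input, grad_weights,
// grad_bias
// [[Rcpp::export]]
List conv2d_backward(NumericVector input, NumericVector weights,
                     NumericVector grad_out) {
  IntegerVector di = input.attr("dim");
  IntegerVector dw = weights.attr("dim");
  const int H = di[0], W = di[1], Cin = di[2], N = di[3];
  const int k = dw[0], Cout = dw[3];
  const int pad = k / 2;
  NumericVector gin((R_xlen_t)H * W * Cin * N);
  gin.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector gw((R_xlen_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector gb(Cout);
  const double *in = input.begin(), *wt = weights.begin(),
               *go = grad_out.begin();
  double *gi = gin.begin(), *gwp = gw.begin(), *gbp = gb.begin();
  const long sIn_c = (long)H * W, sIn_n = (long)H * W * Cin;
  const long sW_ci = (long)k * k, sW_co = (long)k * k * Cin;
  const long sO_c = (long)H * W, sO_n = (long)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double *gop = go + n * sO_n + co * sO_c;
      double acc = 0.0;
      for (long i = 0; i < sO_c; ++i) acc += gop[i];
      gbp[co] += acc;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *ip = in + n * sIn_n + ci * sIn_c;
        double *gip = gi + n * sIn_n + ci * sIn_c;
        const double *wp = wt + co * sW_co + ci * sW_ci;
        double *gwc = gwp + co * sW_co + ci * sW_ci;
        for (int kw = 0; kw < k; ++kw) {
          for (int kh = 0; kh < k; ++kh) {
            const double w0 = wp[kh + k * kw];
            const int dh = kh - pad, dw2 = kw - pad;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const int w0c = std::max(0, -dw2), w1c = std::min(W, W - dw2);
            double gacc = 0.0;
            for (int w2 = w0c; w2 < w1c; ++w2) {
              const double *icol = ip + (long)(w2 + dw2) * H + dh;
              double *gicol = gip + (long)(w2 + dw2) * H + dh;
              const double *gocol = gop + (long)w2 * H;
              for (int h = h0; h < h1; ++h) {
                gacc += gocol[h] * icol[h];
                gicol[h] += gocol[h] * w0;
              }
            }
            gwc[kh + k * kw] += gacc;
          }
        }
      }
    }
  }
  return List::create(Named("grad_input") = gin,
                      Named("grad_weights") = gw,
                      Named("grad_bias") = gb);
}

// 4-connected component labeling of a logical mask; labels 1..K in
// first-encounter (column-major scan) order, 0 for background.
// [[Rcpp::export]]
IntegerMatrix label_components_4(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  IntegerMatrix lab(H, W);
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      const int up = (r > 0 && mask(r - 1, c)) ? lab(r - 1, c) : 0;
      const int left = (c > 0 && mask(r, c - 1)) ? lab(r, c - 1) : 0;
      if (!up && !left) {
        parent.push_back(++next);
        lab(r, c) = next;
      } else if (up && left) {
        lab(r, c) = std::min(find(up), find(left));
        unite(up, left);
      } else {
        lab(r, c) = up ? find(up) : find(left);
      }
    }
  }
  // compact labels in first-encounter order of their roots
  std::vector<int> remap(next + 1, 0);
  int K = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c)) {
        int root = find(lab(r, c));
        if (!remap[root]) remap[root] = ++K;
        lab(r, c) = remap[root];
      }
  return lab;
}

// column sums of the image rotated by each angle (degrees) about its
// center, bilinear sampling, zero fill — the Radon projection used for
// skew search. Returns side x n_angles.
// [[Rcpp::export]]
NumericMatrix rotate_colsums(NumericMatrix mat, NumericVector angles_deg) {
  const int H = mat.nrow(), W = mat.ncol();
  const double cy = (1.0 + H) / 2.0, cx = (1.0 + W) / 2.0;
  NumericMatrix out(W, angles_deg.size());
  const double *m = mat.begin();
  for (int a = 0; a < angles_deg.size(); ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ca = std::cos(th), sa = std::sin(th);
    for (int c = 0; c < W; ++c) {
      const double dx = (c + 1) - cx;
      double acc = 0.0;
      for (int r = 0; r < H; ++r) {
        const double dy = (r + 1) - cy;
        const double xs = cx + ca * dx - sa * dy;
        const double ys = cy + sa * dx + ca * dy;
        const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        if (x0 < 1 || y0 < 1 || x0 > W - 1 || y0 > H - 1) continue;
        const double fx = xs - x0, fy = ys - y0;
        const double *base = m + (long)(x0 - 1) * H + (y0 - 1);
        acc += base[0] * (1 - fx) * (1 - fy) + base[1] * (1 - fx) * fy +
               base[H] * fx * (1 - fy) + base[H + 1] * fx * fy;
      }
      out(c, a) = acc;
    }
  }
  return out;
}
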