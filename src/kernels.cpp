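// Compiled kernels for the native segmentation networks and mask labeling.
// Tensor layout everywhere: column-major R arrays dim (H, W, C, N).
// Convolutions are stride-1, odd square kernel, zero "same" padding, optional
// dilation; implemented as im2col + BLAS matmul per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col(const double* xn, int H, int W, int Ci, int k,
                          int dilation, arma::mat& M) {
  const int pad = dilation * (k - 1) / 2;
  M.zeros();
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = xn + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * (kw + k * ci);
        const int dh = dilation * kh - pad;
        const int dw = dilation * kw - pad;
        double* Mc = M.colptr(col);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        for (int ww = w0; ww < w1; ++ww) {
          const double* src = xc + (size_t)(ww + dw) * H + dh;
          double* dst = Mc + (size_t)ww * H;
          for (int hh = h0; hh < h1; ++hh) dst[hh] = src[hh];
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static inline void col2im(const arma::mat& M, int H, int W, int Ci, int k,
                          int dilation, double* gxn) {
  const int pad = dilation * (k - 1) / 2;
  for (int ci = 0; ci < Ci; ++ci) {
    double* gxc = gxn + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * (kw + k * ci);
        const int dh = dilation * kh - pad;
        const int dw = dilation * kw - pad;
        const double* Mc = M.colptr(col);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        for (int ww = w0; ww < w1; ++ww) {
          double* dst = gxc + (size_t)(ww + dw) * H + dh;
          const double* src = Mc + (size_t)ww * H;
          for (int hh = h0; hh < h1; ++hh) dst[hh] += src[hh];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int k = wd[0], Co = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Ci, Co, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Co, false, true);
  NumericVector y((size_t)H * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  arma::mat M((size_t)H * W, (size_t)k * k * Ci);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Ci, H, W, Ci, k, dilation, M);
    arma::mat Y(y.begin() + (size_t)n * H * W * Co, (size_t)H * W, Co, false, true);
    Y = M * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int k = wd[0], Co = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Ci, Co, false, true);
  NumericVector gx((size_t)H * W * Ci * N), gw((size_t)k * k * Ci * Co);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  arma::mat GW(gw.begin(), k * k * Ci, Co, false, true);
  arma::vec GB(gb.begin(), Co, false, true);
  arma::mat M((size_t)H * W, (size_t)k * k * Ci);
  for (int n = 0; n < N; ++n) {
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)n * H * W * Co,
                 (size_t)H * W, Co, false, true);
    im2col(x.begin() + (size_t)n * H * W * Ci, H, W, Ci, k, dilation, M);
    GW += M.t() * GY;
    GB += arma::sum(GY, 0).t();
    arma::mat GM = GY * Wm.t();
    col2im(GM, H, W, Ci, k, dilation, gx.begin() + (size_t)n * H * W * Ci);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2x2, stride 2 (exact x2 upsampling).
// w dim (2, 2, Ci, Co).
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3], Co = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)H2 * W2 * Co * N);
  y.attr("dim") = IntegerVector::create(H2, W2, Co, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * Ci,
                (size_t)H * W, Ci, false, true);
    double* yn = y.begin() + (size_t)n * H2 * W2 * Co;
    for (int a = 0; a < 2; ++a) {
      for (int bb = 0; bb < 2; ++bb) {
        // weight slice (Ci x Co) at offset (a, bb)
        arma::mat Wab(Ci, Co);
        for (int ci = 0; ci < Ci; ++ci)
          for (int co = 0; co < Co; ++co)
            Wab(ci, co) = w[a + 2 * (bb + 2 * (ci + Ci * co))];
        arma::mat Yab = X * Wab;  // (H*W x Co)
        for (int co = 0; co < Co; ++co) {
          const double* src = Yab.colptr(co);
          double* dst = yn + (size_t)co * H2 * W2;
          for (int ww = 0; ww < W; ++ww)
            for (int hh = 0; hh < H; ++hh)
              dst[(size_t)(2 * ww + bb) * H2 + 2 * hh + a] += src[(size_t)ww * H + hh];
        }
      }
    }
    // bias
    for (int co = 0; co < Co; ++co) {
      double* dst = yn + (size_t)co * H2 * W2;
      const double bc = b[co];
      for (size_t p = 0; p < (size_t)H2 * W2; ++p) dst[p] += bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3], Co = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector gx((size_t)H * W * Ci * N), gw((size_t)4 * Ci * Co), gb(Co);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * Ci,
                (size_t)H * W, Ci, false, true);
    arma::mat GX(gx.begin() + (size_t)n * H * W * Ci, (size_t)H * W, Ci, false, true);
    const double* gyn = gy.begin() + (size_t)n * H2 * W2 * Co;
    for (int a = 0; a < 2; ++a) {
      for (int bb = 0; bb < 2; ++bb) {
        arma::mat GYab((size_t)H * W, Co);
        for (int co = 0; co < Co; ++co) {
          double* dst = GYab.colptr(co);
          const double* src = gyn + (size_t)co * H2 * W2;
          for (int ww = 0; ww < W; ++ww)
            for (int hh = 0; hh < H; ++hh)
              dst[(size_t)ww * H + hh] = src[(size_t)(2 * ww + bb) * H2 + 2 * hh + a];
        }
        arma::mat Wab(Ci, Co);
        for (int ci = 0; ci < Ci; ++ci)
          for (int co = 0; co < Co; ++co)
            Wab(ci, co) = w[a + 2 * (bb + 2 * (ci + Ci * co))];
        GX += GYab * Wab.t();
        arma::mat GWab = X.t() * GYab;  // Ci x Co
        for (int ci = 0; ci < Ci; ++ci)
          for (int co = 0; co < Co; ++co)
            gw[a + 2 * (bb + 2 * (ci + Ci * co))] += GWab(ci, co);
      }
    }
    for (int co = 0; co < Co; ++co) {
      const double* src = gyn + (size_t)co * H2 * W2;
      double s = 0.0;
      for (size_t p = 0; p < (size_t)H2 * W2; ++p) s += src[p];
      gb[co] += s;
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; H and W must be even. Records the winning
// offset (0..3 = dh + 2*dw) for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y((size_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  IntegerVector idx((size_t)H2 * W2 * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = xp + (size_t)cn * H * W;
    double* yc = yp + (size_t)cn * H2 * W2;
    int* ic = ip + (size_t)cn * H2 * W2;
    for (int ww = 0; ww < W2; ++ww) {
      for (int hh = 0; hh < H2; ++hh) {
        double best = -std::numeric_limits<double>::infinity();
        int besti = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const double v = xc[(size_t)(2 * ww + dw) * H + 2 * hh + dh];
            if (v > best) { best = v; besti = dh + 2 * dw; }
          }
        yc[(size_t)ww * H2 + hh] = best;
        ic[(size_t)ww * H2 + hh] = besti;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gy,
                               IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (int cn = 0; cn < C * N; ++cn) {
    double* gxc = gx.begin() + (size_t)cn * H * W;
    const double* gyc = gy.begin() + (size_t)cn * H2 * W2;
    const int* ic = idx.begin() + (size_t)cn * H2 * W2;
    for (int ww = 0; ww < W2; ++ww)
      for (int hh = 0; hh < H2; ++hh) {
        const int b = ic[(size_t)ww * H2 + hh];
        const int dh = b % 2, dw = b / 2;
        gxc[(size_t)(2 * ww + dw) * H + 2 * hh + dh] += gyc[(size_t)ww * H2 + hh];
      }
  }
  return gx;
}

// Per-pixel mean and max over channels -> (H, W, 2, N); argmax channel kept
// for backward.
// [[Rcpp::export]]
List cpp_chanpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)H * W * 2 * N);
  y.attr("dim") = IntegerVector::create(H, W, 2, N);
  IntegerVector idx((size_t)H * W * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* ymean = y.begin() + (size_t)n * H * W * 2;
    double* ymax = ymean + (size_t)H * W;
    int* in = idx.begin() + (size_t)n * H * W;
    for (size_t p = 0; p < (size_t)H * W; ++p) {
      double s = 0.0, best = -std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int c = 0; c < C; ++c) {
        const double v = xn[p + (size_t)c * H * W];
        s += v;
        if (v > best) { best = v; bi = c; }
      }
      ymean[p] = s / C;
      ymax[p] = best;
      in[p] = bi;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_chanpool_bwd(IntegerVector idx, NumericVector gy,
                               IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    double* gxn = gx.begin() + (size_t)n * H * W * C;
    const double* gmean = gy.begin() + (size_t)n * H * W * 2;
    const double* gmax = gmean + (size_t)H * W;
    const int* in = idx.begin() + (size_t)n * H * W;
    for (size_t p = 0; p < (size_t)H * W; ++p) {
      const double gm = gmean[p] / C;
      for (int c = 0; c < C; ++c) gxn[p + (size_t)c * H * W] += gm;
      gxn[p + (size_t)in[p] * H * W] += gmax[p];
    }
  }
  return gx;
}

// Connected-component labeling of a logical matrix; labels assigned in
// raster-scan (column-major) discovery order starting at 1, background 0.
// connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  const int dh4[] = {-1, 1, 0, 0}, dw4[] = {0, 0, -1, 1};
  const int dh8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dw8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dh = connectivity == 8 ? dh8 : dh4;
  const int* dw = connectivity == 8 ? dw8 : dw4;
  const int nd = connectivity == 8 ? 8 : 4;
  int next = 0;
  for (int ww = 0; ww < W; ++ww) {
    for (int hh = 0; hh < H; ++hh) {
      if (!mask(hh, ww) || lab(hh, ww) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({hh, ww});
      lab(hh, ww) = next;
      while (!stack.empty()) {
        const auto pq = stack.back();
        stack.pop_back();
        for (int d = 0; d < nd; ++d) {
          const int nh = pq.first + dh[d], nw = pq.second + dw[d];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (mask(nh, nw) && lab(nh, nw) == 0) {
            lab(nh, nw) = next;
            stack.push_back({nh, nw});
          }
        }
      }
    }
  }
  return lab;
}

// Batch norm over (H, W, N) per channel. Returns y, xhat and per-channel sd
// (the backward pass needs both).
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * N;
  NumericVector y(x.size()), xhat(x.size()), sdv(C);
  y.attr("dim") = xd;
  xhat.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * hw;
      for (size_t p = 0; p < hw; ++p) { s += xc[p]; s2 += xc[p] * xc[p]; }
    }
    const double mu = s / m;
    double va = s2 / m - mu * mu;
    if (va < 0) va = 0;
    const double sd = std::sqrt(va + eps);
    sdv[c] = sd;
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* xc = x.begin() + off;
      double* xh = xhat.begin() + off;
      double* yc = y.begin() + off;
      for (size_t p = 0; p < hw; ++p) {
        xh[p] = (xc[p] - mu) / sd;
        yc[p] = g * xh[p] + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["sd"] = sdv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector xhat, NumericVector sdv, NumericVector gamma,
                NumericVector gy) {
  IntegerVector xd = xhat.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * N;
  NumericVector gx(xhat.size()), ggamma(C), gbeta(C);
  gx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* gc = gy.begin() + off;
      const double* xh = xhat.begin() + off;
      for (size_t p = 0; p < hw; ++p) { sg += gc[p]; sgx += gc[p] * xh[p]; }
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    const double g = gamma[c];
    const double mg = g * sg / m, mgx = g * sgx / m, sd = sdv[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* gc = gy.begin() + off;
      const double* xh = xhat.begin() + off;
      double* gxc = gx.begin() + off;
      for (size_t p = 0; p < hw; ++p) {
        gxc[p] = (g * gc[p] - mg - xh[p] * mgx) / sd;
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector y, NumericVector g) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  for (R_xlen_t i = 0; i < g.size(); ++i) gx[i] = y[i] > 0 ? g[i] : 0.0;
  return gx;
}
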