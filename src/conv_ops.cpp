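// Low-level kernels for the layer graph: 2-D convolution (stride 1, "same"
// zero padding), 2x2 max pooling, and 2x2 nearest-neighbour upsampling,
// each with the matching backward pass.  Tensors cross the R boundary as
// double arrays in (H, W, C) layout; arithmetic runs in single precision
// through BLAS so that desk-scale training stays fast on one core.
//
// The im2col buffer is laid out pixel-major (H*W rows, k^2*C columns):
// fills and spills then walk contiguous memory, the kernel tensor
// (k, k, Cin, Cout) maps onto the GEMM operand without any copy, and the
// GEMM output (H*W x Cout) is already in (H, W, C) order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// col(HW x k2C): col(i + H*j, n + k*m + k2*c) = x[(i+n-p) + H*(j+m-p) + HW*c]
static void im2col_px(const float *x, int H, int W, int C, int k,
                      arma::fmat &col) {
  const int p = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    for (int m = 0; m < k; ++m) {
      for (int n = 0; n < k; ++n) {
        const int q = n + k * m + k * k * c;
        float *dst0 = col.colptr(q);
        const float *src0 = x + HW * c;
        for (int j = 0; j < W; ++j) {
          const int js = j + m - p;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, p - n), i1 = std::min(H, H + p - n);
          float *dst = dst0 + (size_t)H * j;
          const float *src = src0 + (size_t)H * js + (n - p);
          for (int i = i0; i < i1; ++i) dst[i] = src[i];
        }
      }
    }
  }
}

static void col2im_px(const arma::fmat &colg, int H, int W, int C, int k,
                      float *dx) {
  const int p = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int m = 0; m < k; ++m) {
      for (int n = 0; n < k; ++n) {
        const int q = n + k * m + k * k * c;
        const float *src0 = colg.colptr(q);
        float *dst0 = dx + HW * c;
        for (int j = 0; j < W; ++j) {
          const int js = j + m - p;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, p - n), i1 = std::min(H, H + p - n);
          const float *src = src0 + (size_t)H * j;
          float *dst = dst0 + (size_t)H * js + (n - p);
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

static arma::fvec to_float(const NumericVector &v) {
  arma::fvec x(v.size());
  std::copy(v.begin(), v.end(), x.memptr());
  return x;
}

// activation codes: 0 linear, 1 relu, 2 sigmoid
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector K,
                             NumericVector b, int activation) {
  IntegerVector xd = x.attr("dim"), kd = K.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = kd[0], Cout = kd[3];
  if (kd[1] != k || kd[2] != Cin)
    stop("kernel dimensions inconsistent with input channels");
  const size_t HW = (size_t)H * W;
  arma::fvec xf = to_float(x), Kf = to_float(K);
  arma::fmat Wm(Kf.memptr(), (size_t)k * k * Cin, Cout, false, true);
  arma::fmat out;
  if (k == 1) {
    arma::fmat xm(xf.memptr(), HW, Cin, false, true);
    out = xm * Wm;
  } else {
    arma::fmat col(HW, (size_t)k * k * Cin);
    im2col_px(xf.memptr(), H, W, Cin, k, col);
    out = col * Wm;
  }
  for (int o = 0; o < Cout; ++o) out.col(o) += (float)b[o];
  if (activation == 1) out.transform([](float v) { return v > 0.f ? v : 0.f; });
  if (activation == 2) out.transform([](float v) { return 1.f / (1.f + std::exp(-v)); });
  NumericVector res(HW * Cout);
  std::copy(out.begin(), out.end(), res.begin());
  res.attr("dim") = IntegerVector::create(H, W, Cout);
  return res;
}

// dout is the gradient w.r.t. the pre-activation for linear/sigmoid callers,
// or w.r.t. the activation output for relu (masked here using `out`).
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector K, NumericVector out,
                    NumericVector dout, int activation, bool need_dx) {
  IntegerVector xd = x.attr("dim"), kd = K.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = kd[0], Cout = kd[3];
  const size_t HW = (size_t)H * W;
  arma::fmat dz(HW, Cout);
  if (activation == 1) {
    for (size_t t = 0; t < HW * Cout; ++t)
      dz[t] = out[t] > 0 ? (float)dout[t] : 0.f;
  } else {
    for (size_t t = 0; t < HW * Cout; ++t) dz[t] = (float)dout[t];
  }
  arma::fvec xf = to_float(x), Kf = to_float(K);
  arma::fmat Wm(Kf.memptr(), (size_t)k * k * Cin, Cout, false, true);

  arma::fmat dW;
  List res;
  if (k == 1) {
    arma::fmat xm(xf.memptr(), HW, Cin, false, true);
    dW = xm.t() * dz;
  } else {
    arma::fmat col(HW, (size_t)k * k * Cin);
    im2col_px(xf.memptr(), H, W, Cin, k, col);
    dW = col.t() * dz;
  }
  NumericVector dK(K.size());
  std::copy(dW.begin(), dW.end(), dK.begin());
  dK.attr("dim") = kd;
  NumericVector dbv(Cout);
  for (int o = 0; o < Cout; ++o) dbv[o] = arma::accu(dz.col(o));
  res["dK"] = dK;
  res["db"] = dbv;
  if (need_dx) {
    arma::fmat colg = dz * Wm.t();   // HW x k2Cin
    NumericVector dxr(HW * Cin);
    if (k == 1) {
      std::copy(colg.begin(), colg.end(), dxr.begin());
    } else {
      arma::fvec dxf(HW * Cin, arma::fill::zeros);
      col2im_px(colg, H, W, Cin, k, dxf.memptr());
      std::copy(dxf.begin(), dxf.end(), dxr.begin());
    }
    dxr.attr("dim") = IntegerVector::create(H, W, Cin);
    res["dx"] = dxr;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C);
  IntegerVector idx((size_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double *xs = &x[(size_t)H * W * c];
    double *os = &out[(size_t)Ho * Wo * c];
    int *is = &idx[(size_t)Ho * Wo * c];
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -1e300; int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = xs[(2 * i + di) + (size_t)H * (2 * j + dj)];
            if (v > best) { best = v; bi = di + 2 * dj; }
          }
        os[i + (size_t)Ho * j] = best;
        is[i + (size_t)Ho * j] = bi;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(Named("out") = out, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dout, IntegerVector idx,
                               int H, int W) {
  IntegerVector dd = dout.attr("dim");
  const int Ho = dd[0], Wo = dd[1], C = dd[2];
  NumericVector dx((size_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    const double *ds = &dout[(size_t)Ho * Wo * c];
    const int *is = &idx[(size_t)Ho * Wo * c];
    double *xs = &dx[(size_t)H * W * c];
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int b = is[i + (size_t)Ho * j];
        xs[(2 * i + b % 2) + (size_t)H * (2 * j + b / 2)] +=
            ds[i + (size_t)Ho * j];
      }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double *xs = &x[(size_t)H * W * c];
    double *os = &out[(size_t)Ho * Wo * c];
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = xs[i + (size_t)H * j];
        os[(2 * i) + (size_t)Ho * (2 * j)] = v;
        os[(2 * i + 1) + (size_t)Ho * (2 * j)] = v;
        os[(2 * i) + (size_t)Ho * (2 * j + 1)] = v;
        os[(2 * i + 1) + (size_t)Ho * (2 * j + 1)] = v;
      }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dout) {
  IntegerVector dd = dout.attr("dim");
  const int Ho = dd[0], Wo = dd[1], C = dd[2];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    const double *ds = &dout[(size_t)Ho * Wo * c];
    double *xs = &dx[(size_t)H * W * c];
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        xs[i + (size_t)H * j] =
            ds[(2 * i) + (size_t)Ho * (2 * j)] +
            ds[(2 * i + 1) + (size_t)Ho * (2 * j)] +
            ds[(2 * i) + (size_t)Ho * (2 * j + 1)] +
            ds[(2 * i + 1) + (size_t)Ho * (2 * j + 1)];
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
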