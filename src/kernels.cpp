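// Low-level numerical kernels for the convolutional correction networks and
// the windowed SSIM metric. Tensors are column-major R arrays laid out as
// (H, W, C, N): index = h + H*w + H*W*c + H*W*C*n.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fill M (H*W x k*k*C) with the im2col expansion of one sample.
// Column order: c*k*k + dy*k + dx; zero padding of (k-1)/2 on each side.
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& M) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + HW * c;
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        double* m = M.colptr((size_t)c * k * k + (size_t)dy * k + dx);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dx - pad;
          double* mcol = m + (size_t)H * w;
          if (iw < 0 || iw >= W) {
            std::fill(mcol, mcol + H, 0.0);
          } else {
            const double* xcol = xc + (size_t)H * iw;
            for (int h = 0; h < H; ++h) {
              const int ih = h + dy - pad;
              mcol[h] = (ih < 0 || ih >= H) ? 0.0 : xcol[ih];
            }
          }
        }
      }
    }
  }
}

// Scatter-add the col2im inverse of GX (H*W x k*k*C) into gx.
static void col2im_add(const arma::mat& GX, int H, int W, int C, int k, double* gx) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + HW * c;
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const double* m = GX.colptr((size_t)c * k * k + (size_t)dy * k + dx);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dx - pad;
          if (iw < 0 || iw >= W) continue;
          const double* mcol = m + (size_t)H * w;
          double* gcol = gc + (size_t)H * iw;
          for (int h = 0; h < H; ++h) {
            const int ih = h + dy - pad;
            if (ih >= 0 && ih < H) gcol[ih] += mcol[h];
          }
        }
      }
    }
  }
}

// Same-padded stride-1 convolution. W is (k*k*Cin) x Cout, b length Cout.
// [[Rcpp::export]]
NumericVector nn_conv_fw(NumericVector x, IntegerVector dims, NumericMatrix W,
                         NumericVector b, int k) {
  const int H = dims[0], Wd = dims[1], C = dims[2], N = dims[3];
  const int F = W.ncol();
  if (W.nrow() != k * k * C) stop("weight matrix does not match input channels");
  const size_t HW = (size_t)H * Wd;
  NumericVector out((R_xlen_t)(HW * F * N));
  out.attr("dim") = IntegerVector::create(H, Wd, F, N);
  arma::mat Wm(W.begin(), W.nrow(), F, false);
  arma::mat M(HW, (size_t)k * k * C);
  arma::rowvec bv(b.begin(), F);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + HW * C * n, H, Wd, C, k, M);
    arma::mat O(out.begin() + HW * F * n, HW, F, false, true);
    O = M * Wm;
    O.each_row() += bv;
  }
  return out;
}

// Backward pass of nn_conv_fw: returns grads wrt input, weights and bias.
// [[Rcpp::export]]
List nn_conv_bw(NumericVector x, IntegerVector dims, NumericMatrix W, int k,
                NumericVector gout) {
  const int H = dims[0], Wd = dims[1], C = dims[2], N = dims[3];
  const int F = W.ncol();
  const size_t HW = (size_t)H * Wd;
  NumericVector gx((R_xlen_t)(HW * C * N));
  gx.attr("dim") = dims;
  arma::mat Wm(W.begin(), W.nrow(), F, false);
  arma::mat gW(W.nrow(), F, arma::fill::zeros);
  arma::rowvec gb(F, arma::fill::zeros);
  arma::mat M(HW, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + HW * C * n, H, Wd, C, k, M);
    arma::mat G(gout.begin() + HW * F * n, HW, F, false);
    gW += M.t() * G;
    gb += arma::sum(G, 0);
    arma::mat GX = G * Wm.t();
    col2im_add(GX, H, Wd, C, k, gx.begin() + HW * C * n);
  }
  NumericMatrix gWr(W.nrow(), F);
  std::copy(gW.begin(), gW.end(), gWr.begin());
  NumericVector gbr(F);
  std::copy(gb.begin(), gb.end(), gbr.begin());
  return List::create(_["gx"] = gx, _["gW"] = gWr, _["gb"] = gbr);
}

// 2x2 max pooling, stride 2. Returns pooled values and 0-based argmax
// indices into the input vector (for the backward scatter).
// [[Rcpp::export]]
List nn_maxpool_fw(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  if (H % 2 || W % 2) stop("max pooling requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  const size_t no = (size_t)Ho * Wo * C * N;
  NumericVector out((R_xlen_t)no), idx((R_xlen_t)no);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  double* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = base + (size_t)(2 * w) * H + 2 * h;
          size_t best = i00;
          double v = xp[i00];
          const size_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > v) { v = xp[cand[t]]; best = cand[t]; }
          op[o] = v;
          ip[o] = (double)best;
          ++o;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bw(NumericVector gout, NumericVector idx, IntegerVector dims_in) {
  NumericVector gx((R_xlen_t)((size_t)dims_in[0] * dims_in[1] * dims_in[2] * dims_in[3]));
  gx.attr("dim") = dims_in;
  double* g = gx.begin();
  for (R_xlen_t i = 0; i < gout.size(); ++i) g[(size_t)idx[i]] += gout[i];
  return gx;
}

struct LinIdx {
  std::vector<int> i0, i1;
  std::vector<double> t;
};

// Half-pixel-centre mapping for a x2 bilinear resize of axis length L.
static LinIdx up2_index(int L) {
  LinIdx li;
  li.i0.resize(2 * L); li.i1.resize(2 * L); li.t.resize(2 * L);
  for (int i = 0; i < 2 * L; ++i) {
    double src = (i + 0.5) / 2.0 - 0.5;
    int f = (int)std::floor(src);
    double t = src - f;
    int a = std::min(std::max(f, 0), L - 1);
    int b = std::min(std::max(f + 1, 0), L - 1);
    li.i0[i] = a; li.i1[i] = b; li.t[i] = t;
  }
  return li;
}

// Bilinear x2 upsampling (align_corners = FALSE convention).
// [[Rcpp::export]]
NumericVector nn_upsample_fw(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((R_xlen_t)((size_t)Ho * Wo * C * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  LinIdx ry = up2_index(H), rx = up2_index(W);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((size_t)n * C + c) * H * W;
      double* oc = op + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        const double tx = rx.t[w];
        const double* c0 = xc + (size_t)rx.i0[w] * H;
        const double* c1 = xc + (size_t)rx.i1[w] * H;
        double* ocol = oc + (size_t)w * Ho;
        for (int h = 0; h < Ho; ++h) {
          const double ty = ry.t[h];
          ocol[h] = (1 - ty) * ((1 - tx) * c0[ry.i0[h]] + tx * c1[ry.i0[h]]) +
                    ty * ((1 - tx) * c0[ry.i1[h]] + tx * c1[ry.i1[h]]);
        }
      }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector nn_upsample_bw(NumericVector gout, IntegerVector dims_in) {
  const int H = dims_in[0], W = dims_in[1], C = dims_in[2], N = dims_in[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((R_xlen_t)((size_t)H * W * C * N));
  gx.attr("dim") = dims_in;
  LinIdx ry = up2_index(H), rx = up2_index(W);
  const double* gp = gout.begin();
  double* g = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gc = g + ((size_t)n * C + c) * H * W;
      const double* oc = gp + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        const double tx = rx.t[w];
        double* c0 = gc + (size_t)rx.i0[w] * H;
        double* c1 = gc + (size_t)rx.i1[w] * H;
        const double* ocol = oc + (size_t)w * Ho;
        for (int h = 0; h < Ho; ++h) {
          const double ty = ry.t[h], v = ocol[h];
          c0[ry.i0[h]] += (1 - ty) * (1 - tx) * v;
          c1[ry.i0[h]] += (1 - ty) * tx * v;
          c0[ry.i1[h]] += ty * (1 - tx) * v;
          c1[ry.i1[h]] += ty * tx * v;
        }
      }
    }
  return gx;
}

// Valid-region 2-D cross-correlation of a matrix with a small kernel
// (used for the Gaussian-windowed SSIM statistics).
// [[Rcpp::export]]
NumericMatrix conv2_valid(NumericMatrix A, NumericMatrix K) {
  arma::mat Am(A.begin(), A.nrow(), A.ncol(), false);
  arma::mat Km(K.begin(), K.nrow(), K.ncol(), false);
  arma::mat Kf = arma::fliplr(arma::flipud(Km));  // conv2 flips; undo for correlation
  if (A.nrow() < K.nrow() || A.ncol() < K.ncol())
    stop("image smaller than the filter window");
  arma::mat full = arma::conv2(Am, Kf, "full");
  arma::mat valid = full.submat(K.nrow() - 1, K.ncol() - 1, A.nrow() - 1, A.ncol() - 1);
  NumericMatrix out(valid.n_rows, valid.n_cols);
  std::copy(valid.begin(), valid.end(), out.begin());
  return out;
}
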