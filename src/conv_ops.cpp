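// Minimal conv-net kernels: batched 2D convolution, transposed convolution,
// pixel shuffle and max pooling, each with an explicit adjoint so the R side
// can run manual backpropagation. Tensors are arma::cube (H x W x B*C); the
// channel c of batch item b lives in slice b*C + c. Convolution weights are
// matrices of shape O x (Cin*k*k) with column index c*k*k + kj*k + ki, and
// im2col columns are indexed oi + oj*Ho (column-major over the output grid).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static void im2col(const cube& x, uword s0, uword Cin, int k, int stride, int pad,
                   int Ho, int Wo, mat& col) {
  const int H = x.n_rows, W = x.n_cols;
  col.zeros();
  for (uword c = 0; c < Cin; ++c) {
    const mat& xc = x.slice(s0 + c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const uword r = c * k * k + (uword)kj * k + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            col(r, (uword)oi + (uword)oj * Ho) = xc(ii, jj);
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add columns back onto the image planes.
static void col2im_add(const mat& col, cube& x, uword s0, uword Cin, int k,
                       int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols;
  for (uword c = 0; c < Cin; ++c) {
    mat& xc = x.slice(s0 + c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const uword r = c * k * k + (uword)kj * k + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            xc(ii, jj) += col(r, (uword)oi + (uword)oj * Ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube& x, const arma::mat& W, const arma::vec& b,
                       int Cin, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const uword B = x.n_slices / Cin;
  const uword O = W.n_rows;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  cube y(Ho, Wo, B * O);
  mat col(Cin * k * k, (uword)Ho * Wo);
  for (uword bb = 0; bb < B; ++bb) {
    im2col(x, bb * Cin, Cin, k, stride, pad, Ho, Wo, col);
    mat ym = W * col;
    ym.each_col() += b;
    for (uword o = 0; o < O; ++o)
      y.slice(bb * O + o) = reshape(ym.row(o).t(), Ho, Wo);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube& x, const arma::mat& W, const arma::cube& gy,
                       int Cin, int k, int stride, int pad) {
  const uword B = x.n_slices / Cin;
  const uword O = W.n_rows;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(O, fill::zeros);
  mat col(Cin * k * k, (uword)Ho * Wo);
  mat gym(O, (uword)Ho * Wo);
  for (uword bb = 0; bb < B; ++bb) {
    im2col(x, bb * Cin, Cin, k, stride, pad, Ho, Wo, col);
    for (uword o = 0; o < O; ++o)
      gym.row(o) = vectorise(gy.slice(bb * O + o)).t();
    gW += gym * col.t();
    gb += sum(gym, 1);
    mat gcol = W.t() * gym;
    col2im_add(gcol, gx, bb * Cin, Cin, k, stride, pad, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Transposed convolution: weights Wt are Cin x (Cout*k*k); output spatial side
// is (H-1)*stride + k - 2*pad (the inverse of the conv size arithmetic).
// [[Rcpp::export]]
arma::cube nn_convT_fwd(const arma::cube& x, const arma::mat& Wt, const arma::vec& b,
                        int Cin, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const uword B = x.n_slices / Cin;
  const uword Cout = Wt.n_cols / ((uword)k * k);
  const int Ho = (H - 1) * stride + k - 2 * pad;
  const int Wo = (Wd - 1) * stride + k - 2 * pad;
  cube y(Ho, Wo, B * Cout, fill::zeros);
  mat xm(Cin, (uword)H * Wd);
  for (uword bb = 0; bb < B; ++bb) {
    for (uword c = 0; c < (uword)Cin; ++c)
      xm.row(c) = vectorise(x.slice(bb * Cin + c)).t();
    mat gcol = Wt.t() * xm;
    col2im_add(gcol, y, bb * Cout, Cout, k, stride, pad, H, Wd);
    for (uword o = 0; o < Cout; ++o)
      y.slice(bb * Cout + o) += b(o);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_convT_bwd(const arma::cube& x, const arma::mat& Wt, const arma::cube& gy,
                        int Cin, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const uword B = x.n_slices / Cin;
  const uword Cout = Wt.n_cols / ((uword)k * k);
  cube gx(H, Wd, x.n_slices);
  mat gWt(Wt.n_rows, Wt.n_cols, fill::zeros);
  vec gb(Cout, fill::zeros);
  mat col(Cout * k * k, (uword)H * Wd);
  mat xm(Cin, (uword)H * Wd);
  for (uword bb = 0; bb < B; ++bb) {
    im2col(gy, bb * Cout, Cout, k, stride, pad, H, Wd, col);
    mat gxm = Wt * col;
    for (uword c = 0; c < (uword)Cin; ++c) {
      gx.slice(bb * Cin + c) = reshape(gxm.row(c).t(), H, Wd);
      xm.row(c) = vectorise(x.slice(bb * Cin + c)).t();
    }
    gWt += xm * col.t();
    for (uword o = 0; o < Cout; ++o)
      gb(o) += accu(gy.slice(bb * Cout + o));
  }
  return List::create(_["gx"] = gx, _["gW"] = gWt, _["gb"] = gb);
}

// Sub-pixel rearrangement: (H, W, B*Cin) -> (H*r, W*r, B*Cout), Cin = Cout*r^2.
// Pure value rearrangement, no interpolation.
// [[Rcpp::export]]
arma::cube nn_pixel_shuffle(const arma::cube& x, int r, int Cin) {
  const int H = x.n_rows, W = x.n_cols;
  const uword B = x.n_slices / Cin;
  const uword Cout = (uword)Cin / ((uword)r * r);
  cube y(H * r, W * r, B * Cout);
  for (uword bb = 0; bb < B; ++bb)
    for (uword c = 0; c < Cout; ++c)
      for (int i = 0; i < r; ++i)
        for (int j = 0; j < r; ++j) {
          const mat& xc = x.slice(bb * Cin + c * r * r + (uword)i * r + j);
          mat& yc = y.slice(bb * Cout + c);
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h)
              yc(h * r + i, w * r + j) = xc(h, w);
        }
  return y;
}

// Exact inverse of nn_pixel_shuffle (also its adjoint).
// [[Rcpp::export]]
arma::cube nn_pixel_unshuffle(const arma::cube& y, int r, int Cout) {
  const int Hr = y.n_rows, Wr = y.n_cols;
  const int H = Hr / r, W = Wr / r;
  const uword B = y.n_slices / Cout;
  const uword Cin = (uword)Cout * r * r;
  cube x(H, W, B * Cin);
  for (uword bb = 0; bb < B; ++bb)
    for (uword c = 0; c < (uword)Cout; ++c)
      for (int i = 0; i < r; ++i)
        for (int j = 0; j < r; ++j) {
          const mat& yc = y.slice(bb * Cout + c);
          mat& xc = x.slice(bb * Cin + c * r * r + (uword)i * r + j);
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h)
              xc(h, w) = yc(h * r + i, w * r + j);
        }
  return x;
}

// [[Rcpp::export]]
Rcpp::List nn_maxpool_fwd(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const uword S = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  cube y(Ho, Wo, S);
  cube idx(Ho, Wo, S);
  for (uword s = 0; s < S; ++s) {
    const mat& xc = x.slice(s);
    for (int oj = 0; oj < Wo; ++oj)
      for (int oi = 0; oi < Ho; ++oi) {
        double best = -datum::inf;
        int bi = -1, bj = -1;
        for (int kj = 0; kj < k; ++kj) {
          const int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            if (xc(ii, jj) > best) { best = xc(ii, jj); bi = ii; bj = jj; }
          }
        }
        y.slice(s)(oi, oj) = best;
        idx.slice(s)(oi, oj) = (double)bi + (double)bj * H;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube nn_maxpool_bwd(const arma::cube& gy, const arma::cube& idx, int H, int W) {
  const uword S = gy.n_slices;
  cube gx(H, W, S, fill::zeros);
  for (uword s = 0; s < S; ++s) {
    const mat& g = gy.slice(s);
    const mat& id = idx.slice(s);
    for (uword j = 0; j < g.n_cols; ++j)
      for (uword i = 0; i < g.n_rows; ++i) {
        const uword lin = (uword)id(i, j);
        gx.slice(s)(lin % H, lin / H) += g(i, j);
      }
  }
  return gx;
}
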