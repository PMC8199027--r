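// Core dense-tensor primitives for the padding-free convolutional backbone.
// Tensors are arma::cube with layout (rows = image y, cols = image x,
// slices = channels); conv weights arrive pre-flattened from R as a
// (kh*kw*cin) x cout matrix whose row order matches R's column-major
// flattening of an array with dim c(kh, kw, cin).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride,
                        int oh, int ow) {
  const int c = x.n_slices;
  arma::mat cols(oh * (long)ow, kh * (long)kw * c);
  for (int ch = 0; ch < c; ++ch) {
    const arma::mat& sl = x.slice(ch);
    for (int cc = 0; cc < kw; ++cc) {
      for (int rr = 0; rr < kh; ++rr) {
        const long k = rr + kh * ((long)cc + kw * (long)ch);
        double* dst = cols.colptr(k);
        for (int oj = 0; oj < ow; ++oj) {
          const double* src = sl.colptr(oj * stride + cc) + rr;
          for (int oi = 0; oi < oh; ++oi)
            dst[oi + (long)oh * oj] = src[oi * stride];
        }
      }
    }
  }
  return cols;
}

static void col2im_add(arma::cube& gx, const arma::mat& gcols, int kh, int kw,
                       int stride, int oh, int ow) {
  const int c = gx.n_slices;
  for (int ch = 0; ch < c; ++ch) {
    arma::mat& sl = gx.slice(ch);
    for (int cc = 0; cc < kw; ++cc) {
      for (int rr = 0; rr < kh; ++rr) {
        const long k = rr + kh * ((long)cc + kw * (long)ch);
        const double* src = gcols.colptr(k);
        for (int oj = 0; oj < ow; ++oj) {
          double* dst = sl.colptr(oj * stride + cc) + rr;
          for (int oi = 0; oi < oh; ++oi)
            dst[oi * stride] += src[oi + (long)oh * oj];
        }
      }
    }
  }
}

// Valid (no padding) cross-correlation of x with cout filters; W is
// (kh*kw*cin) x cout. Output cube (oh, ow, cout).
// [[Rcpp::export]]
arma::cube cpp_conv_forward(const arma::cube& x, const arma::mat& W,
                            const arma::vec& bias, int kh, int kw,
                            int stride) {
  if ((int)x.n_rows < kh || (int)x.n_cols < kw)
    stop("input smaller than kernel");
  if ((int)W.n_rows != kh * kw * (int)x.n_slices)
    stop("weight rows do not match kernel geometry");
  const int oh = ((int)x.n_rows - kh) / stride + 1;
  const int ow = ((int)x.n_cols - kw) / stride + 1;
  arma::mat cols = im2col(x, kh, kw, stride, oh, ow);
  arma::mat out = cols * W;               // (oh*ow) x cout
  out.each_row() += bias.t();
  arma::cube y(oh, ow, W.n_cols);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_backward(const arma::cube& x, const arma::mat& W,
                       const arma::cube& gout, int kh, int kw, int stride,
                       bool need_gx) {
  const int oh = gout.n_rows, ow = gout.n_cols;
  arma::mat cols = im2col(x, kh, kw, stride, oh, ow);
  arma::mat G(const_cast<double*>(gout.memptr()), oh * (long)ow,
              gout.n_slices, false, true);
  arma::mat gW = cols.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::cube gx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  if (need_gx) {
    arma::mat gcols = G * W.t();
    col2im_add(gx, gcols, kh, kw, stride, oh, ow);
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Max pooling; idx records, per output cell, the linear (row + h*col) index
// of the chosen input cell within its slice. Ties go to the first cell in
// column-major scan order, which keeps the forward pass deterministic.
// [[Rcpp::export]]
List cpp_maxpool_forward(const arma::cube& x, int size, int stride) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int oh = (h - size) / stride + 1, ow = (w - size) / stride + 1;
  arma::cube y(oh, ow, c);
  arma::icube idx(oh, ow, c);
  for (int ch = 0; ch < c; ++ch) {
    const arma::mat& sl = x.slice(ch);
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        double best = -arma::datum::inf;
        long bi = 0;
        for (int cc = 0; cc < size; ++cc) {
          const int col = oj * stride + cc;
          for (int rr = 0; rr < size; ++rr) {
            const int row = oi * stride + rr;
            const double v = sl(row, col);
            if (v > best) { best = v; bi = row + (long)h * col; }
          }
        }
        y(oi, oj, ch) = best;
        idx(oi, oj, ch) = bi;
      }
    }
  }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const arma::cube& gout, const arma::icube& idx,
                                int h, int w) {
  const int c = gout.n_slices;
  arma::cube gx(h, w, c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    arma::mat& sl = gx.slice(ch);
    const arma::mat& g = gout.slice(ch);
    const arma::imat& id = idx.slice(ch);
    for (arma::uword j = 0; j < g.n_cols; ++j)
      for (arma::uword i = 0; i < g.n_rows; ++i)
        sl(id(i, j)) += g(i, j);
  }
  return gx;
}

// Bilinear crop-and-resize of a square window of side `side` (image pixels)
// centred at (cx, cy), 0-based pixel-centre coordinates, to out x out.
// Sample centres are cx + (j - (out-1)/2) * side/out, so an odd-sized
// output centred on an integer pixel with side == out reproduces the
// source pixels exactly. Samples falling outside the image contribute
// `fill`.
// [[Rcpp::export]]
arma::mat cpp_crop_resize(const arma::mat& img, double cx, double cy,
                          double side, int out, double fill) {
  const int h = img.n_rows, w = img.n_cols;
  arma::mat res(out, out);
  const double step = side / out;
  const double half = (out - 1) / 2.0;
  for (int j = 0; j < out; ++j) {
    const double sx = cx + (j - half) * step;
    const int x0 = (int)std::floor(sx);
    const double fx = sx - x0;
    for (int i = 0; i < out; ++i) {
      const double sy = cy + (i - half) * step;
      const int y0 = (int)std::floor(sy);
      const double fy = sy - y0;
      double acc = 0.0;
      for (int dy = 0; dy <= 1; ++dy) {
        const int yy = y0 + dy;
        const double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          const int xx = x0 + dx;
          const double wx = dx ? fx : 1.0 - fx;
          const double v = (yy >= 0 && yy < h && xx >= 0 && xx < w)
                               ? img(yy, xx)
                               : fill;
          acc += wy * wx * v;
        }
      }
      res(i, j) = acc;
    }
  }
  return res;
}

static inline double cubic_w(double t) {
  // Catmull-Rom (a = -0.5); weights sum to 1 so constants are preserved.
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return ((a + 2.0) * t - (a + 3.0)) * t * t + 1.0;
  if (t < 2.0) return ((a * t - 5.0 * a) * t + 8.0 * a) * t - 4.0 * a;
  return 0.0;
}

// Bicubic upsampling by an integer factor with corner-aligned sampling:
// output index u maps to input coordinate u / factor, so the output is
// ((n-1)*factor + 1) per axis and every input sample is reproduced exactly.
// [[Rcpp::export]]
arma::mat cpp_upsample_bicubic(const arma::mat& m, int factor) {
  if (factor < 1) stop("upsample factor must be >= 1");
  if (factor == 1) return m;
  const int h = m.n_rows, w = m.n_cols;
  const int oh = (h - 1) * factor + 1, ow = (w - 1) * factor + 1;
  // pass 1: rows
  arma::mat tmp(oh, w);
  for (int j = 0; j < w; ++j) {
    for (int u = 0; u < oh; ++u) {
      const double s = (double)u / factor;
      const int s0 = (int)std::floor(s);
      double acc = 0.0;
      for (int k = -1; k <= 2; ++k) {
        int idx = s0 + k;
        if (idx < 0) idx = 0;
        if (idx > h - 1) idx = h - 1;
        acc += cubic_w(s - (s0 + k)) * m(idx, j);
      }
      tmp(u, j) = acc;
    }
  }
  arma::mat outm(oh, ow);
  for (int u = 0; u < ow; ++u) {
    const double s = (double)u / factor;
    const int s0 = (int)std::floor(s);
    double wk[4];
    int ik[4];
    for (int k = -1; k <= 2; ++k) {
      int idx = s0 + k;
      if (idx < 0) idx = 0;
      if (idx > w - 1) idx = w - 1;
      wk[k + 1] = cubic_w(s - (s0 + k));
      ik[k + 1] = idx;
    }
    for (int i = 0; i < oh; ++i) {
      double acc = 0.0;
      for (int k = 0; k < 4; ++k) acc += wk[k] * tmp(i, ik[k]);
      outm(i, u) = acc;
    }
  }
  return outm;
}
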