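// Low-level numerical kernels for the segmentation-network engine.
// Feature maps are column-major 4D arrays [H, W, C, N] (R's native layout);
// convolution weights are [k, k, Cin, Cout]; all convolutions are same-padded.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector alloc4(int H, int W, int C, int N) {
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

static inline IntegerVector alloc4i(int H, int W, int C, int N) {
  IntegerVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array [H,W,C,N]");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample: rows ordered (di, dj, ci), columns ordered (h, w).
// Zero padding outside the image (same padding, odd k).
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& cols) {
  const int p = k / 2;
  // cols is (k*k*C) x (H*W)
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = di + k * (dj + k * ci);
        double* out = cols.memptr() + row; // stride k*k*C between columns
        const int rs = cols.n_rows;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dj - p;
          if (sw < 0 || sw >= W) {
            for (int h = 0; h < H; ++h) out[(size_t)rs * (h + (size_t)H * w)] = 0.0;
          } else {
            const double* col = xc + (size_t)sw * H;
            for (int h = 0; h < H; ++h) {
              const int sh = h + di - p;
              out[(size_t)rs * (h + (size_t)H * w)] =
                (sh < 0 || sh >= H) ? 0.0 : col[sh];
            }
          }
        }
      }
    }
  }
}

// col2im: scatter-add the column buffer back onto an image gradient.
static void col2im(const arma::mat& cols, int H, int W, int C, int k, double* dx) {
  const int p = k / 2;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (size_t)ci * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = di + k * (dj + k * ci);
        const double* in = cols.memptr() + row;
        const int rs = cols.n_rows;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dj - p;
          if (sw < 0 || sw >= W) continue;
          double* col = xc + (size_t)sw * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + di - p;
            if (sh < 0 || sh >= H) continue;
            col[sh] += in[(size_t)rs * (h + (size_t)H * w)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector Wt, NumericVector b) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = Wt.attr("dim");
  const int k = wd[0], Ci = wd[2], Co = wd[3];
  if (wd[1] != k || Ci != C) stop("weight dims do not match input");
  arma::mat Wm(Wt.begin(), (size_t)k * k * Ci, Co, false, true);
  NumericVector y = alloc4(H, W, Co, N);
  arma::mat cols((size_t)k * k * Ci, (size_t)H * W);
  arma::vec bv(b.begin(), Co, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    arma::mat ym(y.begin() + (size_t)n * H * W * Co, (size_t)H * W, Co, false, true);
    ym = cols.t() * Wm;
    ym.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector Wt, NumericVector dy) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = Wt.attr("dim");
  const int k = wd[0], Ci = wd[2], Co = wd[3];
  arma::mat Wm(Wt.begin(), (size_t)k * k * Ci, Co, false, true);
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dW = alloc4(k, k, Ci, Co);
  NumericVector db(Co);
  arma::mat dWm(dW.begin(), (size_t)k * k * Ci, Co, false, true);
  arma::vec dbv(db.begin(), Co, false, true);
  arma::mat cols((size_t)k * k * Ci, (size_t)H * W);
  arma::mat dcols((size_t)k * k * Ci, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    arma::mat dym(dy.begin() + (size_t)n * H * W * Co, (size_t)H * W, Co, false, true);
    dWm += cols * dym;
    dbv += arma::sum(dym, 0).t();
    dcols = Wm * dym.t();
    col2im(dcols, H, W, C, k, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 stride-2 transposed convolution (non-overlapping): weights [2,2,Cin,Cout].
// [[Rcpp::export]]
NumericVector tconv2_fw_cpp(NumericVector x, NumericVector Wt, NumericVector b) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = Wt.attr("dim");
  const int Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("weight dims do not match input");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = alloc4(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* yn = y.begin() + (size_t)n * Ho * Wo * Co;
    for (int co = 0; co < Co; ++co) {
      double* yc = yn + (size_t)co * Ho * Wo;
      const double bias = b[co];
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] = bias;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xn + (size_t)ci * H * W;
        const double w00 = Wt[0 + 2 * 0 + 4 * (ci + (size_t)Ci * co)];
        const double w10 = Wt[1 + 2 * 0 + 4 * (ci + (size_t)Ci * co)];
        const double w01 = Wt[0 + 2 * 1 + 4 * (ci + (size_t)Ci * co)];
        const double w11 = Wt[1 + 2 * 1 + 4 * (ci + (size_t)Ci * co)];
        for (int w = 0; w < W; ++w) {
          for (int h = 0; h < H; ++h) {
            const double v = xc[h + (size_t)H * w];
            double* base = yc + (size_t)(2 * h) + (size_t)Ho * (2 * w);
            base[0]      += v * w00;
            base[1]      += v * w10;
            base[Ho]     += v * w01;
            base[Ho + 1] += v * w11;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List tconv2_bw_cpp(NumericVector x, NumericVector Wt, NumericVector dy) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = Wt.attr("dim");
  const int Ci = wd[2], Co = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dW = alloc4(2, 2, Ci, Co);
  NumericVector db(Co);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Co;
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int co = 0; co < Co; ++co) {
      const double* dyc = dyn + (size_t)co * Ho * Wo;
      double dbsum = 0.0;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dbsum += dyc[i];
      db[co] += dbsum;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xn + (size_t)ci * H * W;
        double* dxc = dxn + (size_t)ci * H * W;
        const size_t wi = 4 * (ci + (size_t)Ci * co);
        const double w00 = Wt[wi], w10 = Wt[wi + 1], w01 = Wt[wi + 2], w11 = Wt[wi + 3];
        double g00 = 0, g10 = 0, g01 = 0, g11 = 0;
        for (int w = 0; w < W; ++w) {
          for (int h = 0; h < H; ++h) {
            const double* base = dyc + (size_t)(2 * h) + (size_t)Ho * (2 * w);
            const double d00 = base[0], d10 = base[1], d01 = base[Ho], d11 = base[Ho + 1];
            const double v = xc[h + (size_t)H * w];
            g00 += v * d00; g10 += v * d10; g01 += v * d01; g11 += v * d11;
            dxc[h + (size_t)H * w] += w00 * d00 + w10 * d10 + w01 * d01 + w11 * d11;
          }
        }
        dW[wi] += g00; dW[wi + 1] += g10; dW[wi + 2] += g01; dW[wi + 3] += g11;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 stride-2 max pooling; idx stores the within-window argmax (0..3).
// [[Rcpp::export]]
List maxpool2_fw_cpp(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = x.begin() + cn * H * W;
    double* yc = y.begin() + cn * Ho * Wo;
    int* ic = idx.begin() + cn * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const double* base = xc + (size_t)(2 * h) + (size_t)H * (2 * w);
        double best = base[0]; int bi = 0;
        if (base[1] > best) { best = base[1]; bi = 1; }
        if (base[H] > best) { best = base[H]; bi = 2; }
        if (base[H + 1] > best) { best = base[H + 1]; bi = 3; }
        yc[h + (size_t)Ho * w] = best;
        ic[h + (size_t)Ho * w] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw_cpp(NumericVector dy, IntegerVector idx, int H, int W) {
  int Ho, Wo, C, N; get_dims4(dy, Ho, Wo, C, N);
  NumericVector dx = alloc4(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* dyc = dy.begin() + cn * Ho * Wo;
    const int* ic = idx.begin() + cn * Ho * Wo;
    double* dxc = dx.begin() + cn * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int bi = ic[h + (size_t)Ho * w];
        const int dh = bi & 1, dw = bi >> 1;
        dxc[(size_t)(2 * h + dh) + (size_t)H * (2 * w + dw)] += dyc[h + (size_t)Ho * w];
      }
    }
  }
  return dx;
}

// fxf stride-f average pooling.
// [[Rcpp::export]]
NumericVector avgpool_fw_cpp(NumericVector x, int f) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % f || W % f) stop("spatial dims must be divisible by the pooling factor");
  const int Ho = H / f, Wo = W / f;
  const double inv = 1.0 / (f * f);
  NumericVector y = alloc4(Ho, Wo, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = x.begin() + cn * H * W;
    double* yc = y.begin() + cn * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double s = 0.0;
        for (int dw = 0; dw < f; ++dw)
          for (int dh = 0; dh < f; ++dh)
            s += xc[(size_t)(f * h + dh) + (size_t)H * (f * w + dw)];
        yc[h + (size_t)Ho * w] = s * inv;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_bw_cpp(NumericVector dy, int f, int H, int W) {
  int Ho, Wo, C, N; get_dims4(dy, Ho, Wo, C, N);
  const double inv = 1.0 / (f * f);
  NumericVector dx = alloc4(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* dyc = dy.begin() + cn * Ho * Wo;
    double* dxc = dx.begin() + cn * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const double g = dyc[h + (size_t)Ho * w] * inv;
        for (int dw = 0; dw < f; ++dw)
          for (int dh = 0; dh < f; ++dh)
            dxc[(size_t)(f * h + dh) + (size_t)H * (f * w + dw)] += g;
      }
    }
  }
  return dx;
}

// Inverse-mapped affine resampling about the image centre.
// For each output pixel p (1-based grid), the source location is
// A %*% (p - centre) + centre + shift, sampled bilinearly (bilinear = true)
// or at the nearest pixel; out-of-bounds samples read as `fill`.
// [[Rcpp::export]]
NumericMatrix warp_affine_cpp(NumericMatrix img, NumericMatrix A, NumericVector shift,
                              bool bilinear, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double cr = (H + 1) / 2.0, cc = (W + 1) / 2.0;
  const double a11 = A(0, 0), a12 = A(0, 1), a21 = A(1, 0), a22 = A(1, 1);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double dr = (i + 1) - cr, dc = (j + 1) - cc;
      const double sr = a11 * dr + a12 * dc + cr + shift[0];
      const double sc = a21 * dr + a22 * dc + cc + shift[1];
      if (bilinear) {
        const double fr = sr - 1.0, fc = sc - 1.0; // 0-based
        const int r0 = (int)std::floor(fr), c0 = (int)std::floor(fc);
        const double wr = fr - r0, wc = fc - c0;
        double v = 0.0;
        for (int dj2 = 0; dj2 <= 1; ++dj2) {
          for (int di2 = 0; di2 <= 1; ++di2) {
            const int rr = r0 + di2, cc2 = c0 + dj2;
            const double wt = (di2 ? wr : 1 - wr) * (dj2 ? wc : 1 - wc);
            const double px = (rr < 0 || rr >= H || cc2 < 0 || cc2 >= W)
              ? fill : img(rr, cc2);
            v += wt * px;
          }
        }
        out(i, j) = v;
      } else {
        const int rr = (int)std::lround(sr) - 1;
        const int cc2 = (int)std::lround(sc) - 1;
        out(i, j) = (rr < 0 || rr >= H || cc2 < 0 || cc2 >= W) ? fill : img(rr, cc2);
      }
    }
  }
  return out;
}

// Directed nearest-neighbour Euclidean distances between foreground point
// sets of two binary masks; the symmetric Hausdorff distance and its
// percentile variants are reductions of these two vectors.
// [[Rcpp::export]]
List directed_nn_dists_cpp(IntegerMatrix a, IntegerMatrix b) {
  std::vector<double> ar, ac, br, bc;
  for (int j = 0; j < a.ncol(); ++j)
    for (int i = 0; i < a.nrow(); ++i)
      if (a(i, j) != 0) { ar.push_back(i); ac.push_back(j); }
  for (int j = 0; j < b.ncol(); ++j)
    for (int i = 0; i < b.nrow(); ++i)
      if (b(i, j) != 0) { br.push_back(i); bc.push_back(j); }
  const size_t na = ar.size(), nb = br.size();
  if (na == 0 || nb == 0) stop("both masks must be non-empty");
  NumericVector dab(na), dba(nb, R_PosInf);
  for (size_t i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (size_t j = 0; j < nb; ++j) {
      const double d2 = (ar[i] - br[j]) * (ar[i] - br[j]) +
                        (ac[i] - bc[j]) * (ac[i] - bc[j]);
      if (d2 < best) best = d2;
      if (d2 < dba[j]) dba[j] = d2;
    }
    dab[i] = std::sqrt(best);
  }
  for (size_t j = 0; j < nb; ++j) dba[j] = std::sqrt(dba[j]);
  return List::create(_["ab"] = dab, _["ba"] = dba);
}
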