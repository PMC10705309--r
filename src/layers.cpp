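// Low-level CPU layers for the U-net variants.
//
// Tensor convention: a batch is an arma::cube of shape (C, P, N) where C is
// the channel count, P the flattened spatial size (column-major over the
// 2 or 3 spatial axes) and N the batch size. Convolutions are 3^d kernels
// with stride 1 and zero padding 1 ("same"); pooling and transposed
// convolutions use factor 2 per axis. All arithmetic is double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// im2col / col2im
// ---------------------------------------------------------------------------

// Kernel offsets in {-1,0,1}^d, column-major over axes (di fastest).
static inline int n_offsets(int d) { return d == 2 ? 9 : 27; }

// x: (C x P) one sample; col: (C*K x P), must be zeroed by the caller.
static void im2col(const arma::mat& x, arma::mat& col, const int* dim, int d) {
  const int C = x.n_rows;
  if (d == 2) {
    const int H = dim[0], W = dim[1];
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di, ++k) {
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int ilo = (di < 0) ? -di : 0;
          const int ihi = (di > 0) ? H - di : H;
          for (int i = ilo; i < ihi; ++i) {
            const int p = i + j * H, ps = (i + di) + js * H;
            std::memcpy(col.colptr(p) + k * C, x.colptr(ps),
                        C * sizeof(double));
          }
        }
      }
    }
  } else {
    const int H = dim[0], W = dim[1], D = dim[2];
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di, ++k) {
          for (int z = 0; z < D; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= D) continue;
            for (int j = 0; j < W; ++j) {
              const int js = j + dj;
              if (js < 0 || js >= W) continue;
              const int ilo = (di < 0) ? -di : 0;
              const int ihi = (di > 0) ? H - di : H;
              for (int i = ilo; i < ihi; ++i) {
                const int p = i + (j + z * W) * H;
                const int ps = (i + di) + (js + zs * W) * H;
                std::memcpy(col.colptr(p) + k * C, x.colptr(ps),
                            C * sizeof(double));
              }
            }
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add columns of gcol back onto gx (C x P).
static void col2im(const arma::mat& gcol, arma::mat& gx, const int* dim,
                   int d) {
  const int C = gx.n_rows;
  if (d == 2) {
    const int H = dim[0], W = dim[1];
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di, ++k) {
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int ilo = (di < 0) ? -di : 0;
          const int ihi = (di > 0) ? H - di : H;
          for (int i = ilo; i < ihi; ++i) {
            const int p = i + j * H, ps = (i + di) + js * H;
            double* dst = gx.colptr(ps);
            const double* src = gcol.colptr(p) + k * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  } else {
    const int H = dim[0], W = dim[1], D = dim[2];
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di, ++k) {
          for (int z = 0; z < D; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= D) continue;
            for (int j = 0; j < W; ++j) {
              const int js = j + dj;
              if (js < 0 || js >= W) continue;
              const int ilo = (di < 0) ? -di : 0;
              const int ihi = (di > 0) ? H - di : H;
              for (int i = ilo; i < ihi; ++i) {
                const int p = i + (j + z * W) * H;
                const int ps = (i + di) + (js + zs * W) * H;
                double* dst = gx.colptr(ps);
                const double* src = gcol.colptr(p) + k * C;
                for (int c = 0; c < C; ++c) dst[c] += src[c];
              }
            }
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Convolution (3^d kernel, stride 1, pad 1)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".conv_forward")]]
arma::cube conv_forward(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, IntegerVector dim) {
  const int d = dim.size(), C = x.n_rows, P = x.n_cols, N = x.n_slices;
  const int K = n_offsets(d), Cout = W.n_rows;
  if ((int)W.n_cols != C * K) stop("conv_forward: weight shape mismatch");
  arma::cube y(Cout, P, N);
  arma::mat col(C * K, P);
  for (int n = 0; n < N; ++n) {
    col.zeros();
    im2col(x.slice(n), col, dim.begin(), d);
    y.slice(n) = W * col;
    y.slice(n).each_col() += b;
  }
  return y;
}

// [[Rcpp::export(name = ".conv_backward")]]
List conv_backward(const arma::cube& x, const arma::cube& gy,
                   const arma::mat& W, IntegerVector dim) {
  const int d = dim.size(), C = x.n_rows, P = x.n_cols, N = x.n_slices;
  const int K = n_offsets(d);
  arma::cube gx(C, P, N, arma::fill::zeros);
  arma::mat gW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec gb(W.n_rows, arma::fill::zeros);
  arma::mat col(C * K, P);
  for (int n = 0; n < N; ++n) {
    col.zeros();
    im2col(x.slice(n), col, dim.begin(), d);
    gW += gy.slice(n) * col.t();
    gb += arma::sum(gy.slice(n), 1);
    arma::mat gcol = W.t() * gy.slice(n);
    col2im(gcol, gx.slice(n), dim.begin(), d);
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Max pooling (factor 2 per axis)
// ---------------------------------------------------------------------------

// Flat input indices of the 2^d pooling block for output position q.
static void pool_block(int q, const int* dim, int d, int* out) {
  if (d == 2) {
    const int H = dim[0];
    const int Ho = H / 2;
    const int i = q % Ho, j = q / Ho;
    int t = 0;
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di)
        out[t++] = (2 * i + di) + (2 * j + dj) * H;
  } else {
    const int H = dim[0], W = dim[1];
    const int Ho = H / 2, Wo = W / 2;
    const int i = q % Ho, j = (q / Ho) % Wo, z = q / (Ho * Wo);
    int t = 0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          out[t++] = (2 * i + di) + ((2 * j + dj) + (2 * z + dz) * W) * H;
  }
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward(const arma::cube& x, IntegerVector dim) {
  const int d = dim.size(), C = x.n_rows, N = x.n_slices;
  int Po = 1;
  for (int a = 0; a < d; ++a) {
    if (dim[a] % 2 != 0) stop("maxpool: spatial dims must be even");
    Po *= dim[a] / 2;
  }
  const int B = 1 << d;
  arma::cube y(C, Po, N);
  arma::ucube idx(C, Po, N);
  std::vector<int> blk(B);
  for (int n = 0; n < N; ++n) {
    const arma::mat& xs = x.slice(n);
    for (int q = 0; q < Po; ++q) {
      pool_block(q, dim.begin(), d, blk.data());
      for (int c = 0; c < C; ++c) {
        double best = xs(c, blk[0]);
        int besti = blk[0];
        for (int t = 1; t < B; ++t) {
          const double v = xs(c, blk[t]);
          if (v > best) { best = v; besti = blk[t]; }
        }
        y(c, q, n) = best;
        idx(c, q, n) = besti;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
arma::cube maxpool_backward(const arma::cube& gy, const arma::ucube& idx,
                            int P_in) {
  const int C = gy.n_rows, Po = gy.n_cols, N = gy.n_slices;
  arma::cube gx(C, P_in, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int q = 0; q < Po; ++q)
      for (int c = 0; c < C; ++c)
        gx(c, idx(c, q, n), n) += gy(c, q, n);
  return gx;
}

// ---------------------------------------------------------------------------
// Transposed convolution (2^d kernel, stride 2: exact upsampling by 2)
// ---------------------------------------------------------------------------

// Output flat index for input position p and block offset t.
static void up_targets(int p, const int* dim, int d, int* out) {
  if (d == 2) {
    const int H = dim[0];
    const int i = p % H, j = p / H;
    const int H2 = 2 * H;
    int t = 0;
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di)
        out[t++] = (2 * i + di) + (2 * j + dj) * H2;
  } else {
    const int H = dim[0], W = dim[1];
    const int i = p % H, j = (p / H) % W, z = p / (H * W);
    const int H2 = 2 * H, W2 = 2 * W;
    int t = 0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          out[t++] = (2 * i + di) + ((2 * j + dj) + (2 * z + dz) * W2) * H2;
  }
}

// W: (Cout*2^d) x Cin, block t occupies rows [t*Cout, (t+1)*Cout).
// [[Rcpp::export(name = ".upconv_forward")]]
arma::cube upconv_forward(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, IntegerVector dim) {
  const int d = dim.size(), P = x.n_cols, N = x.n_slices;
  const int B = 1 << d, Cout = W.n_rows / B;
  arma::cube y(Cout, P * B, N);
  std::vector<int> tgt(B);
  for (int n = 0; n < N; ++n) {
    arma::mat tmp = W * x.slice(n);  // (Cout*B) x P
    arma::mat& ys = y.slice(n);
    for (int p = 0; p < P; ++p) {
      up_targets(p, dim.begin(), d, tgt.data());
      for (int t = 0; t < B; ++t) {
        double* dst = ys.colptr(tgt[t]);
        const double* src = tmp.colptr(p) + t * Cout;
        for (int c = 0; c < Cout; ++c) dst[c] = src[c] + b(c);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upconv_backward")]]
List upconv_backward(const arma::cube& x, const arma::cube& gy,
                     const arma::mat& W, IntegerVector dim) {
  const int d = dim.size(), C = x.n_rows, P = x.n_cols, N = x.n_slices;
  const int B = 1 << d, Cout = W.n_rows / B;
  arma::cube gx(C, P, N);
  arma::mat gW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  std::vector<int> tgt(B);
  arma::mat gtmp(Cout * B, P);
  for (int n = 0; n < N; ++n) {
    const arma::mat& gys = gy.slice(n);
    for (int p = 0; p < P; ++p) {
      up_targets(p, dim.begin(), d, tgt.data());
      for (int t = 0; t < B; ++t) {
        const double* src = gys.colptr(tgt[t]);
        double* dst = gtmp.colptr(p) + t * Cout;
        for (int c = 0; c < Cout; ++c) dst[c] = src[c];
      }
    }
    gW += gtmp * x.slice(n).t();
    gx.slice(n) = W.t() * gtmp;
    gb += arma::sum(gy.slice(n), 1);  // bias reaches every output element
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Batch normalization (per channel over batch x spatial)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".bn_forward")]]
List bn_forward(const arma::cube& x, const arma::vec& gamma,
                const arma::vec& beta, double eps) {
  const int C = x.n_rows, P = x.n_cols, N = x.n_slices;
  const double M = (double)P * N;
  arma::vec mu(C, arma::fill::zeros), v(C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) mu += arma::sum(x.slice(n), 1);
  mu /= M;
  for (int n = 0; n < N; ++n) {
    arma::mat cen = x.slice(n);
    cen.each_col() -= mu;
    v += arma::sum(arma::square(cen), 1);
  }
  v /= M;  // biased variance, standard for BN
  arma::vec inv = 1.0 / arma::sqrt(v + eps);
  arma::cube y(C, P, N);
  for (int n = 0; n < N; ++n) {
    arma::mat t = x.slice(n);
    t.each_col() -= mu;
    t.each_col() %= inv % gamma;
    t.each_col() += beta;
    y.slice(n) = t;
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = v);
}

// [[Rcpp::export(name = ".bn_forward_inference")]]
arma::cube bn_forward_inference(const arma::cube& x, const arma::vec& gamma,
                                const arma::vec& beta, const arma::vec& rmean,
                                const arma::vec& rvar, double eps) {
  const int C = x.n_rows, P = x.n_cols, N = x.n_slices;
  arma::vec inv = 1.0 / arma::sqrt(rvar + eps);
  arma::cube y(C, P, N);
  for (int n = 0; n < N; ++n) {
    arma::mat t = x.slice(n);
    t.each_col() -= rmean;
    t.each_col() %= inv % gamma;
    t.each_col() += beta;
    y.slice(n) = t;
  }
  return y;
}

// [[Rcpp::export(name = ".bn_backward")]]
List bn_backward(const arma::cube& x, const arma::cube& gy,
                 const arma::vec& gamma, const arma::vec& mu,
                 const arma::vec& v, double eps) {
  const int C = x.n_rows, P = x.n_cols, N = x.n_slices;
  const double M = (double)P * N;
  arma::vec inv = 1.0 / arma::sqrt(v + eps);
  arma::vec sum_gy(C, arma::fill::zeros), sum_gy_xhat(C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat xhat = x.slice(n);
    xhat.each_col() -= mu;
    xhat.each_col() %= inv;
    sum_gy += arma::sum(gy.slice(n), 1);
    sum_gy_xhat += arma::sum(gy.slice(n) % xhat, 1);
  }
  arma::cube gx(C, P, N);
  arma::vec coef = gamma % inv / M;
  for (int n = 0; n < N; ++n) {
    arma::mat xhat = x.slice(n);
    xhat.each_col() -= mu;
    xhat.each_col() %= inv;
    arma::mat t = M * gy.slice(n);
    t.each_col() -= sum_gy;
    xhat.each_col() %= sum_gy_xhat;
    t -= xhat;
    t.each_col() %= coef;
    gx.slice(n) = t;
  }
  return List::create(_["gx"] = gx, _["ggamma"] = sum_gy_xhat,
                      _["gbeta"] = sum_gy);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (separable parabola method),
// anisotropic voxel spacing supported. Used for HD95 surface distances.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& dst, int n,
                 double w) {
  // lower envelope of parabolas y = (x - i*w)^2 + f[i]
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> vtx(n);
  std::vector<double> z(n + 1);
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {  // no sites on this line
    for (int q = 0; q < n; ++q) dst[q] = INF;
    return;
  }
  int k = 0;
  vtx[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      const int p = vtx[k];
      s = ((f[q] + (double)q * q * w2) - (f[p] + (double)p * p * w2)) /
          (2.0 * w2 * (q - p));
      if (s <= z[k]) {
        if (k == 0) { vtx[0] = q; z[1] = INF; break; }
        --k;
      } else {
        ++k;
        vtx[k] = q;
        z[k] = s;
        z[k + 1] = INF;
        break;
      }
    }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < (double)q) ++kk;
    const int p = vtx[kk];
    const double dxy = ((double)q - p) * w;
    dst[q] = dxy * dxy + f[p];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  static const double INF = std::numeric_limits<double>::infinity();
  const int nd = dim.size();
  int total = 1;
  for (int a = 0; a < nd; ++a) total *= dim[a];
  NumericVector out(total);
  for (int i = 0; i < total; ++i) out[i] = mask[i] ? 0.0 : INF;

  // transform along each axis in turn
  std::vector<int> stride(nd);
  stride[0] = 1;
  for (int a = 1; a < nd; ++a) stride[a] = stride[a - 1] * dim[a - 1];
  for (int a = 0; a < nd; ++a) {
    const int n = dim[a], st = stride[a];
    const int nlines = total / n;
    std::vector<double> f(n), dst(n);
    for (int line = 0; line < nlines; ++line) {
      // base index of this line
      int rem = line, base = 0;
      for (int b = 0; b < nd; ++b) {
        if (b == a) continue;
        const int sz = dim[b];
        base += (rem % sz) * stride[b];
        rem /= sz;
      }
      bool any = false;
      for (int q = 0; q < n; ++q) {
        f[q] = out[base + q * st];
        if (f[q] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, dst, n, spacing[a]);
      for (int q = 0; q < n; ++q) out[base + q * st] = dst[q];
    }
  }
  out.attr("dim") = dim;
  return out;
}
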