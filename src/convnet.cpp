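// Convolution and pooling kernels for the spectrogram CNN. Activations are
// stored as cubes of shape (H, W, C*B), image-major: slice b*C + c holds
// channel c of image b. Convolutions use same zero padding and stride 1.
// The forward pass is a single batched im2col + GEMM; the backward pass the
// transpose GEMM plus col2im scatter. The im2col buffer is reused across
// calls and only its zero-padding border is cleared, which keeps the kernels
// memory-bandwidth- rather than allocation-bound.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// batched im2col: rows = B*H*W patches (image-major), cols = C*k*k
static void im2col_batch(const cube& X, int C, int B, int k, mat& cols) {
  const int H = X.n_rows, W = X.n_cols, pad = (k - 1) / 2;
  for (int b = 0; b < B; ++b) {
    const int row0 = b * H * W;
    for (int c = 0; c < C; ++c) {
      const mat& S = X.slice(b * C + c);
      int col = c * k * k;
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di, ++col) {
          double* dst = cols.colptr(col);
          const int i_lo = std::max(0, pad - di);
          const int i_hi = std::min(H - 1, H - 1 + pad - di);
          const int len = i_hi - i_lo + 1;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - pad;
            double* d = dst + row0 + j * H;
            if (sj < 0 || sj >= W) {          // fully padded stripe
              std::memset(d, 0, H * sizeof(double));
              continue;
            }
            if (i_lo > 0) std::memset(d, 0, i_lo * sizeof(double));
            if (i_hi < H - 1) {
              std::memset(d + i_hi + 1, 0, (H - 1 - i_hi) * sizeof(double));
            }
            std::memcpy(d + i_lo, S.colptr(sj) + (i_lo + di - pad),
                        len * sizeof(double));
          }
        }
      }
    }
  }
}

// batched col2im scatter-add, inverse indexing of im2col_batch
static void col2im_batch(cube& dX, int C, int B, int k, const mat& dcols) {
  const int H = dX.n_rows, W = dX.n_cols, pad = (k - 1) / 2;
  for (int b = 0; b < B; ++b) {
    const int row0 = b * H * W;
    for (int c = 0; c < C; ++c) {
      mat& S = dX.slice(b * C + c);
      int col = c * k * k;
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di, ++col) {
          const double* src = dcols.colptr(col);
          const int i_lo = std::max(0, pad - di);
          const int i_hi = std::min(H - 1, H - 1 + pad - di);
          const int len = i_hi - i_lo + 1;
          if (len <= 0) continue;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - pad;
            if (sj < 0 || sj >= W) continue;
            double* dst = S.colptr(sj) + (i_lo + di - pad);
            const double* s = src + row0 + j * H + i_lo;
            for (int t = 0; t < len; ++t) dst[t] += s[t];
          }
        }
      }
    }
  }
}

// scratch storage shared across calls (single-threaded use); layer sizes
// alternate, so the backing vector only ever grows and mats alias into it
static mat scratch_cols(size_t rows, size_t cols_n) {
  static std::vector<double> buf;
  if (buf.size() < rows * cols_n) buf.resize(rows * cols_n);
  return mat(buf.data(), rows, cols_n, false, true);
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& X, const arma::mat& Wt,
                          int C, int B, int k) {
  const int H = X.n_rows, W = X.n_cols, F = Wt.n_cols;
  mat cols = scratch_cols(B * H * W, C * k * k);
  im2col_batch(X, C, B, k, cols);
  mat out = cols * Wt;                       // (B*H*W) x F
  cube Y(H, W, F * B);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < F; ++f) {
      std::memcpy(Y.slice(b * F + f).memptr(),
                  out.colptr(f) + b * H * W, H * W * sizeof(double));
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& X, const arma::cube& dY,
                          const arma::mat& Wt, int C, int B, int k,
                          bool need_dx) {
  const int H = X.n_rows, W = X.n_cols, F = Wt.n_cols;
  mat cols = scratch_cols(B * H * W, C * k * k);
  im2col_batch(X, C, B, k, cols);
  mat dYmat(B * H * W, F);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < F; ++f) {
      std::memcpy(dYmat.colptr(f) + b * H * W,
                  dY.slice(b * F + f).memptr(), H * W * sizeof(double));
    }
  }
  mat dW = cols.t() * dYmat;
  if (!need_dx) {
    return Rcpp::List::create(Rcpp::Named("dW") = dW);
  }
  mat dcols = dYmat * Wt.t();                // (B*H*W) x (C*k*k)
  cube dX(H, W, C * B, fill::zeros);
  col2im_batch(dX, C, B, k, dcols);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("dX") = dX);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const arma::cube& X, int p) {
  const int H = X.n_rows, W = X.n_cols, S = X.n_slices;
  const int Ho = H / p, Wo = W / p;
  cube Y(Ho, Wo, S);
  ucube idx(Ho, Wo, S);                      // linear index within slice
  for (int s = 0; s < S; ++s) {
    const mat& M = X.slice(s);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < p; ++dj) {
          for (int di = 0; di < p; ++di) {
            const int ii = i * p + di, jj = j * p + dj;
            const double v = M(ii, jj);
            if (v > best) { best = v; bi = jj * H + ii; }
          }
        }
        Y(i, j, s) = best;
        idx(i, j, s) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::ucube& idx, const arma::cube& dY,
                           int H, int W) {
  const int S = dY.n_slices, Ho = dY.n_rows, Wo = dY.n_cols;
  cube dX(H, W, S, fill::zeros);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        dX.slice(s)(idx(i, j, s)) += dY(i, j, s);
      }
    }
  }
  return dX;
}

// ---------------------------------------------------------------------------
// Whole-path kernels: residual blocks (conv-BN-ReLU pairs with 1x1 bypass),
// optional 2x2 pooling, and the per-path fully connected layer, with an
// in-C++ cache between forward and backward to avoid R round-trips.

struct BlockCache {
  cube cur, a1, pre;     // block input, first activation, pre-ReLU sum
  cube xh1, xh2, xhs;    // batch-norm normalized activations
  vec is1, is2, iss;     // batch-norm inverse standard deviations
  ucube pool_idx;
  int Hin = 0, Win = 0;
};

struct PathCache {
  std::vector<BlockCache> blocks;
  mat Xflat, h_pre;
  int Hl = 0, Wl = 0, Cl = 0;
};

static std::map<int, PathCache> g_path_cache;

// batch norm over channels of an image-major cube (slice b*F + f)
static void bn_fwd_cpp(const cube& Z, int F, int B, const vec& gamma,
                       const vec& beta, vec& run_mean, vec& run_var,
                       bool train, double momentum, double eps,
                       cube& Y, cube& xhat, vec& invstd) {
  const int HW = Z.n_rows * Z.n_cols;
  const double n = (double) HW * B;
  Y.set_size(arma::size(Z));
  xhat.set_size(arma::size(Z));
  invstd.set_size(F);
  for (int f = 0; f < F; ++f) {
    double mu, va;
    if (train) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        const double* z = Z.slice(b * F + f).memptr();
        for (int t = 0; t < HW; ++t) { s += z[t]; s2 += z[t] * z[t]; }
      }
      mu = s / n;
      va = s2 / n - mu * mu;
      run_mean(f) = (1 - momentum) * run_mean(f) + momentum * mu;
      run_var(f) = (1 - momentum) * run_var(f) + momentum * va;
    } else {
      mu = run_mean(f); va = run_var(f);
    }
    const double is = 1.0 / std::sqrt(va + eps);
    invstd(f) = is;
    for (int b = 0; b < B; ++b) {
      const double* z = Z.slice(b * F + f).memptr();
      double* xh = xhat.slice(b * F + f).memptr();
      double* y = Y.slice(b * F + f).memptr();
      for (int t = 0; t < HW; ++t) {
        xh[t] = (z[t] - mu) * is;
        y[t] = gamma(f) * xh[t] + beta(f);
      }
    }
  }
}

// batch-norm backward; returns dZ, accumulates dgamma/dbeta
static cube bn_bwd_cpp(const cube& dY, const cube& xhat, const vec& invstd,
                       const vec& gamma, int F, int B, vec& dgamma,
                       vec& dbeta) {
  const int HW = dY.n_rows * dY.n_cols;
  const double n = (double) HW * B;
  cube dZ(arma::size(dY));
  dgamma.zeros(F); dbeta.zeros(F);
  for (int f = 0; f < F; ++f) {
    double sdy = 0, sdyx = 0;
    for (int b = 0; b < B; ++b) {
      const double* dy = dY.slice(b * F + f).memptr();
      const double* xh = xhat.slice(b * F + f).memptr();
      for (int t = 0; t < HW; ++t) { sdy += dy[t]; sdyx += dy[t] * xh[t]; }
    }
    dgamma(f) = sdyx; dbeta(f) = sdy;
    const double g = gamma(f), is = invstd(f);
    for (int b = 0; b < B; ++b) {
      const double* dy = dY.slice(b * F + f).memptr();
      const double* xh = xhat.slice(b * F + f).memptr();
      double* dz = dZ.slice(b * F + f).memptr();
      for (int t = 0; t < HW; ++t) {
        dz[t] = is / n * (n * g * dy[t] - g * sdy - xh[t] * g * sdyx);
      }
    }
  }
  return dZ;
}

static cube conv_fwd_raw(const cube& X, const mat& Wt, int C, int B, int k) {
  const int H = X.n_rows, W = X.n_cols, F = Wt.n_cols;
  mat cols = scratch_cols(B * H * W, C * k * k);
  im2col_batch(X, C, B, k, cols);
  mat out = cols * Wt;
  cube Y(H, W, F * B);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < F; ++f) {
      std::memcpy(Y.slice(b * F + f).memptr(),
                  out.colptr(f) + b * H * W, H * W * sizeof(double));
    }
  }
  return Y;
}

static void conv_bwd_raw(const cube& X, const cube& dY, const mat& Wt,
                         int C, int B, int k, bool need_dx, mat& dW,
                         cube& dX) {
  const int H = X.n_rows, W = X.n_cols, F = Wt.n_cols;
  mat cols = scratch_cols(B * H * W, C * k * k);
  im2col_batch(X, C, B, k, cols);
  mat dYmat(B * H * W, F);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < F; ++f) {
      std::memcpy(dYmat.colptr(f) + b * H * W,
                  dY.slice(b * F + f).memptr(), H * W * sizeof(double));
    }
  }
  dW = cols.t() * dYmat;
  if (need_dx) {
    mat dcols = dYmat * Wt.t();
    dX.zeros(H, W, C * B);
    col2im_batch(dX, C, B, k, dcols);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_path_fwd(const arma::cube& X, Rcpp::List blocks,
                        const arma::mat& fcW, const arma::vec& fcb,
                        int B, int k, bool pool, bool train,
                        double momentum, double eps, int cache_id) {
  PathCache pc;
  cube cur = X;
  int c_in = 1;
  Rcpp::List new_stats(blocks.size());
  for (int bi = 0; bi < blocks.size(); ++bi) {
    Rcpp::List blk = blocks[bi];
    mat Wa = blk["Wa"], Wb = blk["Wb"], Ws = blk["Ws"];
    vec g1 = blk["g1"], e1 = blk["e1"], g2 = blk["g2"], e2 = blk["e2"],
        gs = blk["gs"], es = blk["es"];
    vec m1 = blk["m1"], v1 = blk["v1"], m2 = blk["m2"], v2 = blk["v2"],
        ms = blk["ms"], vs = blk["vs"];
    const int F = Wa.n_cols;
    BlockCache bc;
    bc.cur = cur;
    cube z1 = conv_fwd_raw(cur, Wa, c_in, B, k);
    cube bn1Y;
    bn_fwd_cpp(z1, F, B, g1, e1, m1, v1, train, momentum, eps,
               bn1Y, bc.xh1, bc.is1);
    bc.a1 = arma::clamp(bn1Y, 0.0, datum::inf);
    cube z2 = conv_fwd_raw(bc.a1, Wb, F, B, k);
    cube bn2Y;
    bn_fwd_cpp(z2, F, B, g2, e2, m2, v2, train, momentum, eps,
               bn2Y, bc.xh2, bc.is2);
    cube zs = conv_fwd_raw(cur, Ws, c_in, B, 1);
    cube bnsY;
    bn_fwd_cpp(zs, F, B, gs, es, ms, vs, train, momentum, eps,
               bnsY, bc.xhs, bc.iss);
    bc.pre = bn2Y + bnsY;
    cube out = arma::clamp(bc.pre, 0.0, datum::inf);
    bc.Hin = out.n_rows; bc.Win = out.n_cols;
    if (pool) {
      const int p = 2, Ho = bc.Hin / p, Wo = bc.Win / p;
      cube Yp(Ho, Wo, out.n_slices);
      bc.pool_idx.set_size(Ho, Wo, out.n_slices);
      for (unsigned s = 0; s < out.n_slices; ++s) {
        const mat& M = out.slice(s);
        for (int j = 0; j < Wo; ++j) {
          for (int i = 0; i < Ho; ++i) {
            double best = -datum::inf; uword bidx = 0;
            for (int dj = 0; dj < p; ++dj) {
              for (int di = 0; di < p; ++di) {
                const double v = M(i * p + di, j * p + dj);
                if (v > best) { best = v; bidx = (j * p + dj) * bc.Hin + i * p + di; }
              }
            }
            Yp(i, j, s) = best;
            bc.pool_idx(i, j, s) = bidx;
          }
        }
      }
      out = Yp;
    }
    if (!train) { bc = BlockCache(); }   // no cache needed at inference
    pc.blocks.push_back(std::move(bc));
    cur = out;
    c_in = F;
    new_stats[bi] = Rcpp::List::create(
      Rcpp::Named("m1") = m1, Rcpp::Named("v1") = v1,
      Rcpp::Named("m2") = m2, Rcpp::Named("v2") = v2,
      Rcpp::Named("ms") = ms, Rcpp::Named("vs") = vs);
  }
  pc.Hl = cur.n_rows; pc.Wl = cur.n_cols; pc.Cl = c_in;
  const int D = pc.Hl * pc.Wl * c_in;
  mat Xflat(B, D);
  for (int b = 0; b < B; ++b) {
    int off = 0;
    for (int c = 0; c < c_in; ++c) {
      const mat& S = cur.slice(b * c_in + c);
      for (int j = 0; j < pc.Wl; ++j) {
        for (int i = 0; i < pc.Hl; ++i) {
          Xflat(b, off++) = S(i, j);
        }
      }
    }
  }
  pc.Xflat = Xflat;
  mat h_pre = Xflat * fcW;
  h_pre.each_row() += fcb.t();
  pc.h_pre = h_pre;
  mat h = arma::clamp(h_pre, 0.0, datum::inf);
  if (train) {
    g_path_cache[cache_id] = std::move(pc);
  }
  return Rcpp::List::create(Rcpp::Named("h") = h,
                            Rcpp::Named("stats") = new_stats);
}

// [[Rcpp::export]]
Rcpp::List cpp_path_bwd(const arma::mat& dh, Rcpp::List blocks,
                        const arma::mat& fcW, int B, int k, bool pool,
                        int cache_id) {
  PathCache& pc = g_path_cache[cache_id];
  mat dh_pre = dh % arma::conv_to<mat>::from(pc.h_pre > 0);
  mat dfcW = pc.Xflat.t() * dh_pre;
  rowvec dfcb = arma::sum(dh_pre, 0);
  mat dflat = dh_pre * fcW.t();
  const int Cl = pc.Cl;
  cube dcur(pc.Hl, pc.Wl, Cl * B);
  for (int b = 0; b < B; ++b) {
    int off = 0;
    for (int c = 0; c < Cl; ++c) {
      mat& S = dcur.slice(b * Cl + c);
      for (int j = 0; j < pc.Wl; ++j) {
        for (int i = 0; i < pc.Hl; ++i) {
          S(i, j) = dflat(b, off++);
        }
      }
    }
  }
  Rcpp::List grads(blocks.size());
  for (int bi = blocks.size() - 1; bi >= 0; --bi) {
    Rcpp::List blk = blocks[bi];
    mat Wa = blk["Wa"], Wb = blk["Wb"], Ws = blk["Ws"];
    vec g1 = blk["g1"], g2 = blk["g2"], gs = blk["gs"];
    const int F = Wa.n_cols;
    BlockCache& bc = pc.blocks[bi];
    const int c_in = bc.cur.n_slices / B;
    if (pool) {
      cube up(bc.Hin, bc.Win, dcur.n_slices, fill::zeros);
      for (unsigned s = 0; s < dcur.n_slices; ++s) {
        for (unsigned j = 0; j < dcur.n_cols; ++j) {
          for (unsigned i = 0; i < dcur.n_rows; ++i) {
            up.slice(s)(bc.pool_idx(i, j, s)) += dcur(i, j, s);
          }
        }
      }
      dcur = up;
    }
    // ReLU mask of the residual sum
    cube dpre = dcur % arma::conv_to<cube>::from(bc.pre > 0);
    vec dg2, de2, dg1, de1, dgs, des;
    cube dz2 = bn_bwd_cpp(dpre, bc.xh2, bc.is2, g2, F, B, dg2, de2);
    mat dWb; cube da1;
    conv_bwd_raw(bc.a1, dz2, Wb, F, B, k, true, dWb, da1);
    da1 %= arma::conv_to<cube>::from(bc.a1 > 0);
    cube dz1 = bn_bwd_cpp(da1, bc.xh1, bc.is1, g1, F, B, dg1, de1);
    const bool need_dx = bi > 0;
    mat dWa; cube dX1;
    conv_bwd_raw(bc.cur, dz1, Wa, c_in, B, k, need_dx, dWa, dX1);
    cube dzs = bn_bwd_cpp(dpre, bc.xhs, bc.iss, gs, F, B, dgs, des);
    mat dWs; cube dXs;
    conv_bwd_raw(bc.cur, dzs, Ws, c_in, B, 1, need_dx, dWs, dXs);
    if (need_dx) dcur = dX1 + dXs;
    grads[bi] = Rcpp::List::create(
      Rcpp::Named("Wa") = dWa, Rcpp::Named("Wb") = dWb,
      Rcpp::Named("Ws") = dWs,
      Rcpp::Named("g1") = dg1, Rcpp::Named("e1") = de1,
      Rcpp::Named("g2") = dg2, Rcpp::Named("e2") = de2,
      Rcpp::Named("gs") = dgs, Rcpp::Named("es") = des);
  }
  g_path_cache.erase(cache_id);
  return Rcpp::List::create(Rcpp::Named("blocks") = grads,
                            Rcpp::Named("fcW") = dfcW,
                            Rcpp::Named("fcb") = dfcb);
}
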