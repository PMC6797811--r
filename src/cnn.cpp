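// Small CNN (3x [conv 5x5 same-padding -> ReLU -> max-pool] -> dropout ->
// FC -> ReLU -> FC -> softmax) forward/backward over a batch, built on
// im2col + BLAS gemm. Convolution weights are stored as
// (C_out x C_in*k*k) matrices; activations as (H x W x C) cubes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col(const cube& act, int k, mat& col) {
  const int H = act.n_rows, W = act.n_cols, C = act.n_slices;
  const int p = (k - 1) / 2;
  col.set_size(C * k * k, H * W);
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const mat& a = act.slice(c);
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int r = c * k * k + (di + p) + (dj + p) * k;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            col(r, i + j * H) = a(i + di, sj);
        }
      }
    }
  }
}

static void col2im(const mat& dcol, int k, int H, int W, int C, cube& dact) {
  const int p = (k - 1) / 2;
  dact.set_size(H, W, C);
  dact.zeros();
  for (int c = 0; c < C; ++c) {
    mat& a = dact.slice(c);
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int r = c * k * k + (di + p) + (dj + p) * k;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            a(i + di, sj) += dcol(r, i + j * H);
        }
      }
    }
  }
}

static void maxpool(const cube& in, int w, cube& out, umat& arg) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int Ho = H / w, Wo = W / w;
  out.set_size(Ho, Wo, C);
  arg.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& a = in.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bidx = 0;
        for (int dj = 0; dj < w; ++dj)
          for (int di = 0; di < w; ++di) {
            const int ii = i * w + di, jj = j * w + dj;
            const double v = a(ii, jj);
            if (v > best) { best = v; bidx = ii + jj * H; }
          }
        out(i, j, c) = best;
        arg(i + j * Ho, c) = bidx;
      }
  }
}

static void maxpool_back(const cube& dout, const umat& arg, int H, int W,
                         cube& din) {
  const int C = dout.n_slices;
  din.set_size(H, W, C);
  din.zeros();
  for (int c = 0; c < C; ++c) {
    const mat& d = dout.slice(c);
    mat& o = din.slice(c);
    for (uword q = 0; q < d.n_elem; ++q) o(arg(q, c)) += d(q);
  }
}

// X: (H x W x batch) input images; y: 1-based class labels (may be empty
// when grad = false); weights: W1,b1,W2,b2,W3,b3,F1,c1,F2,c2; dropout_mask:
// (flat_dim x batch) inverted-dropout multipliers or 0x0 for none.
// [[Rcpp::export]]
Rcpp::List cpp_cnn_batch(const arma::cube& X, const arma::ivec& y,
                         const Rcpp::List& weights, const Rcpp::List& arch,
                         const arma::mat& dropout_mask, bool grad) {
  const ivec channels = Rcpp::as<ivec>(arch["channels"]);
  const ivec pools = Rcpp::as<ivec>(arch["pools"]);
  const int k = Rcpp::as<int>(arch["kernel"]);
  if (channels.n_elem != 3 || pools.n_elem != 3)
    Rcpp::stop("architecture must have exactly 3 conv and 3 pool stages");
  if (k % 2 == 0) Rcpp::stop("kernel size must be odd");

  mat Wc[3], F1, F2;
  vec bc[3], c1, c2;
  for (int l = 0; l < 3; ++l) {
    Wc[l] = Rcpp::as<mat>(weights[2 * l]);
    bc[l] = Rcpp::as<vec>(weights[2 * l + 1]);
  }
  F1 = Rcpp::as<mat>(weights[6]); c1 = Rcpp::as<vec>(weights[7]);
  F2 = Rcpp::as<mat>(weights[8]); c2 = Rcpp::as<vec>(weights[9]);

  const int batch = X.n_slices;
  const int K = F2.n_rows;
  // trace spatial dims
  int Hs[4], Cs[4];
  Hs[0] = X.n_rows; Cs[0] = 1;
  for (int l = 0; l < 3; ++l) {
    Hs[l + 1] = Hs[l] / pools[l];
    Cs[l + 1] = channels[l];
    if (Hs[l + 1] < 1) Rcpp::stop("shape error: feature map collapsed");
    if ((int)Wc[l].n_rows != channels[l] ||
        (int)Wc[l].n_cols != Cs[l] * k * k)
      Rcpp::stop("shape error: conv weight %d is %dx%d, expected %dx%d",
                 l + 1, (int)Wc[l].n_rows, (int)Wc[l].n_cols,
                 (int)channels[l], Cs[l] * k * k);
  }
  const int flat = Hs[3] * Hs[3] * Cs[3];
  if ((int)F1.n_cols != flat)
    Rcpp::stop("shape error: fc1 expects %d inputs, conv/pool output is %d",
               (int)F1.n_cols, flat);
  const bool use_mask = dropout_mask.n_elem > 0;

  mat probs(K, batch);
  double loss = 0.0;
  mat gW[3], gF1, gF2;
  vec gb[3], gc1, gc2;
  if (grad) {
    for (int l = 0; l < 3; ++l) {
      gW[l].zeros(Wc[l].n_rows, Wc[l].n_cols);
      gb[l].zeros(bc[l].n_elem);
    }
    gF1.zeros(F1.n_rows, F1.n_cols); gc1.zeros(c1.n_elem);
    gF2.zeros(F2.n_rows, F2.n_cols); gc2.zeros(c2.n_elem);
  }

  mat cols[3];
  cube acts[4], relus[3], pooled[3];
  umat args[3];
  for (int b = 0; b < batch; ++b) {
    acts[0] = cube(Hs[0], Hs[0], 1);
    acts[0].slice(0) = X.slice(b);
    for (int l = 0; l < 3; ++l) {
      im2col(acts[l], k, cols[l]);
      mat Z = Wc[l] * cols[l];
      Z.each_col() += bc[l];
      Z.transform([](double v) { return v > 0 ? v : 0.0; });
      const int H = acts[l].n_rows;
      mat Zt = Z.t();  // (H*W x C): matches cube column-major layout
      relus[l] = cube(Zt.memptr(), H, H, channels[l]);
      maxpool(relus[l], pools[l], pooled[l], args[l]);
      acts[l + 1] = pooled[l];
    }
    vec flatv(acts[3].memptr(), flat);
    vec flatd = use_mask ? vec(flatv % dropout_mask.col(b)) : flatv;
    vec h = F1 * flatd + c1;
    h.transform([](double v) { return v > 0 ? v : 0.0; });
    vec z = F2 * h + c2;
    z -= z.max();
    vec e = exp(z);
    vec p = e / accu(e);
    probs.col(b) = p;
    if (y.n_elem > (uword)b && y(b) >= 1) {
      loss -= std::log(std::max(p(y(b) - 1), 1e-12));
      if (grad) {
        vec dz = p;
        dz(y(b) - 1) -= 1.0;
        gF2 += dz * h.t();
        gc2 += dz;
        vec dh = F2.t() * dz;
        for (uword i = 0; i < dh.n_elem; ++i) if (h(i) <= 0) dh(i) = 0;
        gF1 += dh * flatd.t();
        gc1 += dh;
        vec dflat = F1.t() * dh;
        if (use_mask) dflat %= dropout_mask.col(b);
        cube dp(dflat.memptr(), Hs[3], Hs[3], Cs[3]);
        for (int l = 2; l >= 0; --l) {
          cube dr;
          maxpool_back(dp, args[l], relus[l].n_rows, relus[l].n_cols, dr);
          const int H = relus[l].n_rows;
          mat dZm(channels[l], H * H);
          // relu mask + reshape cube (H,H,C) -> (C, H*H)
          for (int c = 0; c < channels[l]; ++c)
            for (int q = 0; q < H * H; ++q)
              dZm(c, q) = relus[l].slice(c)(q) > 0 ? dr.slice(c)(q) : 0.0;
          gW[l] += dZm * cols[l].t();
          gb[l] += sum(dZm, 1);
          if (l > 0) {
            mat dcol = Wc[l].t() * dZm;
            col2im(dcol, k, H, H, Cs[l], dp);
          }
        }
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loss") = loss,
                                      Rcpp::Named("probs") = probs);
  if (grad)
    out["grads"] = Rcpp::List::create(gW[0], gb[0], gW[1], gb[1], gW[2],
                                      gb[2], gF1, gc1, gF2, gc2);
  return out;
}
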