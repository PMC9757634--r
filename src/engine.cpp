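// Twin-VAE compute engine: two convolutional variational autoencoders with
// modality-specific outer layers and a shared core (last encoder conv,
// fully connected bottleneck, first transposed-conv decoder stage), plus a
// count-regression head read off the shared decoder output.
//
// Single precision throughout; convolutions run as im2col + sgemm.  All
// stochastic elements (orthogonal init, dropout, reparameterization) draw
// from one engine-owned mt19937_64 stream so runs are reproducible for a
// given seed on a given platform.

#include <RcppArmadillo.h>
#include <memory>
#include <random>
#include <string>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]
// [[Rcpp::plugins(cpp17)]]

using arma::fmat;
using arma::fvec;
using Rcpp::List;

static const int N_PARTS = 8;
static const char* PART_NAMES[N_PARTS] = {
  "outer_encoder_natural", "outer_encoder_synthetic", "shared_encoder",
  "bottleneck", "shared_decoder", "outer_decoder_natural",
  "outer_decoder_synthetic", "regressor"
};

// small fast PRNG for dropout masks (seeded from the engine stream)
struct Xoshiro128 {
  uint32_t s[4] = {1, 2, 3, 4};
  static uint32_t rotl(uint32_t x, int k) { return (x << k) | (x >> (32 - k)); }
  void seed(uint64_t a, uint64_t b) {
    s[0] = (uint32_t)a; s[1] = (uint32_t)(a >> 32);
    s[2] = (uint32_t)b; s[3] = (uint32_t)(b >> 32);
    for (int i = 0; i < 4; ++i) if (s[i] == 0) s[i] = 0x9E3779B9u + i;
    for (int i = 0; i < 8; ++i) next();
  }
  uint32_t next() {
    const uint32_t result = rotl(s[0] + s[3], 7) + s[0];
    const uint32_t t = s[1] << 9;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 11);
    return result;
  }
};

struct Param {
  fmat W, g, m, v;       // value, gradient, Adam first/second moments
  int part;
  std::string name;
  Param(int nr, int nc, int part_, std::string name_)
    : W(nr, nc, arma::fill::zeros), g(nr, nc, arma::fill::zeros),
      m(nr, nc, arma::fill::zeros), v(nr, nc, arma::fill::zeros),
      part(part_), name(std::move(name_)) {}
};

// ---- im2col family -------------------------------------------------------
// Activations are stored as (C, H*W*B) with spatial index p = h + w*H and
// column index b*H*W + p.  Patch matrices are kept transposed,
// (smallHW*B, C*K*K), so each patch-channel is a contiguous column.

static void gatherT(const fmat& large, fmat& colsT,
                    int C, int largeH, int largeW,
                    int smallH, int smallW, int B,
                    int K, int stride, int pad) {
  const int KK = K * K, sHW = smallH * smallW, lHW = largeH * largeW;
  colsT.set_size(sHW * B, C * KK);
  for (int r = 0; r < C * KK; ++r) {
    const int c = r / KK, kw = (r % KK) / K, kh = r % K;
    float* dst = colsT.colptr(r);
    for (int b = 0; b < B; ++b) {
      const float* src = large.memptr() + (size_t)large.n_rows * (size_t)b * lHW + c;
      float* d2 = dst + (size_t)b * sHW;
      for (int ws = 0; ws < smallW; ++ws) {
        const int wl = ws * stride - pad + kw;
        float* d3 = d2 + ws * smallH;
        if (wl < 0 || wl >= largeW) {
          for (int hs = 0; hs < smallH; ++hs) d3[hs] = 0.0f;
          continue;
        }
        const float* s2 = src + (size_t)large.n_rows * (size_t)wl * largeH;
        for (int hs = 0; hs < smallH; ++hs) {
          const int hl = hs * stride - pad + kh;
          d3[hs] = (hl >= 0 && hl < largeH)
            ? s2[(size_t)large.n_rows * hl] : 0.0f;
        }
      }
    }
  }
}

static void scatterT(const fmat& colsT, fmat& large,
                     int C, int largeH, int largeW,
                     int smallH, int smallW, int B,
                     int K, int stride, int pad) {
  const int KK = K * K, sHW = smallH * smallW, lHW = largeH * largeW;
  large.zeros(C, (size_t)lHW * B);
  for (int r = 0; r < C * KK; ++r) {
    const int c = r / KK, kw = (r % KK) / K, kh = r % K;
    const float* src = colsT.colptr(r);
    for (int b = 0; b < B; ++b) {
      float* dst = large.memptr() + (size_t)large.n_rows * (size_t)b * lHW + c;
      const float* s2 = src + (size_t)b * sHW;
      for (int ws = 0; ws < smallW; ++ws) {
        const int wl = ws * stride - pad + kw;
        if (wl < 0 || wl >= largeW) continue;
        float* d2 = dst + (size_t)large.n_rows * (size_t)wl * largeH;
        const float* s3 = s2 + ws * smallH;
        for (int hs = 0; hs < smallH; ++hs) {
          const int hl = hs * stride - pad + kh;
          if (hl >= 0 && hl < largeH) d2[(size_t)large.n_rows * hl] += s3[hs];
        }
      }
    }
  }
}

// ---- layer descriptors ---------------------------------------------------

struct ConvSpec {            // forward convolution (encoder side)
  int Cin, Cout, K, stride, pad, Hin, Win, Hout, Wout;
  Param *W, *b;
};
struct ConvTSpec {           // transposed convolution (decoder side)
  int Cin, Cout, K, stride, pad, opad, Hin, Win, Hout, Wout;
  Param *W, *b;              // W is (Cin, Cout*K*K)
};
struct FcSpec {
  int in, out;
  Param *W, *b;              // W is (out, in)
};

static void conv_fwd(const ConvSpec& L, const fmat& X, fmat& Y, int B,
                     fmat* keep = nullptr) {
  fmat local;
  fmat& colsT = keep ? *keep : local;
  gatherT(X, colsT, L.Cin, L.Hin, L.Win, L.Hout, L.Wout, B, L.K, L.stride, L.pad);
  Y = L.W->W * colsT.t();
  Y.each_col() += L.b->W.col(0);
}

static void conv_bwd(const ConvSpec& L, const fmat* cached, const fmat& X,
                     const fmat& dY, fmat& dX, int B, bool need_dx = true) {
  fmat local;
  const fmat* cp = cached;
  if (!cp) {
    gatherT(X, local, L.Cin, L.Hin, L.Win, L.Hout, L.Wout, B, L.K, L.stride, L.pad);
    cp = &local;
  }
  const fmat& colsT = *cp;
  L.W->g += dY * colsT;
  L.b->g.col(0) += arma::sum(dY, 1);
  if (need_dx) {
    fmat dcolsT = dY.t() * L.W->W;
    scatterT(dcolsT, dX, L.Cin, L.Hin, L.Win, L.Hout, L.Wout, B, L.K, L.stride, L.pad);
  }
}

static void convT_fwd(const ConvTSpec& L, const fmat& X, fmat& Y, int B) {
  fmat colsT = X.t() * L.W->W;              // (HinWinB, Cout*K*K)
  scatterT(colsT, Y, L.Cout, L.Hout, L.Wout, L.Hin, L.Win, B, L.K, L.stride, L.pad);
  Y.each_col() += L.b->W.col(0);
}

static void convT_bwd(const ConvTSpec& L, const fmat& X, const fmat& dY,
                      fmat& dX, int B) {
  fmat dcolsT;
  gatherT(dY, dcolsT, L.Cout, L.Hout, L.Wout, L.Hin, L.Win, B, L.K, L.stride, L.pad);
  L.W->g += X * dcolsT;
  L.b->g.col(0) += arma::sum(dY, 1);
  dX = L.W->W * dcolsT.t();
}

// ---- engine --------------------------------------------------------------

struct Cache {                         // intermediates of the last forward
  int Bn = 0, Bs = 0;
  fmat xin[2];                         // inputs as (1, H*W*Bt)
  fmat eact[2][4], emask[2][4];        // encoder post-activation + dropout mask
  fmat ecols[2][4], scols;             // cached im2col patches (training)
  fmat sact, smask;                    // shared encoder
  fmat h1, m1;                         // fc1 post-activation + mask
  fmat mu, lv, eps, z;
  fmat h2, m2;                         // fc2 post-activation + mask
  fmat sd_in;                          // reshaped fc2 output (Crs, s*s*B)
  fmat bn_xhat; fvec bn_invstd;        // batch-norm cache
  fmat D;                              // shared decoder output, post lrelu
  fmat pooled, r1, rmask, r;           // regressor
  fmat dact[2][5];                     // outer decoder activations (last = recon)
  bool train = false;
};

struct Engine {
  int res = 128, s = 4;                // s: bottleneck spatial side
  double width = 1.0;
  int c32, c64, c128, c256, c512, latent, c128r, Crs;
  int dc[4];                           // outer decoder channel plan
  float slope = 0.2f, drop = 0.1f;
  std::mt19937_64 rng;
  Xoshiro128 fast_rng;
  uint64_t seed = 1;
  long step_count = 0;

  void seed_rngs(uint64_t sd) {
    rng.seed(sd);
    fast_rng.seed(rng(), rng());
  }

  std::vector<std::unique_ptr<Param>> params;
  ConvSpec enc[2][4], senc;
  FcSpec fc1, fcmu, fclv, fc2, rfc1, rfc2;
  ConvTSpec sdec, dec[2][5];
  Param *bn_gamma = nullptr, *bn_beta = nullptr;
  fvec bn_rmean, bn_rvar;              // running statistics (buffers)
  float bn_mom = 0.1f, bn_eps = 1e-5f;

  Cache C;

  Param* add(int nr, int nc, int part, const std::string& nm) {
    params.emplace_back(new Param(nr, nc, part, nm));
    return params.back().get();
  }

  int chan(double x) const {
    int v = (int)std::lround(x * width);
    return v < 1 ? 1 : v;
  }

  void orth_init(fmat& W) {
    const int r = W.n_rows, c = W.n_cols;
    const int big = std::max(r, c), small = std::min(r, c);
    arma::mat G(big, small);
    std::normal_distribution<double> nd(0.0, 1.0);
    for (arma::uword i = 0; i < G.n_elem; ++i) G(i) = nd(rng);
    arma::mat Q, R;
    arma::qr_econ(Q, R, G);
    for (int j = 0; j < small; ++j)
      if (R(j, j) < 0) Q.col(j) *= -1.0;
    arma::mat M = (r >= c) ? Q : arma::mat(Q.t());
    W = arma::conv_to<fmat>::from(M);
  }

  void build(int res_, double width_, Rcpp::IntegerVector dch, uint64_t seed_,
             double drop_, double slope_) {
    res = res_; width = width_; seed = seed_;
    drop = (float)drop_; slope = (float)slope_;
    if (res < 32 || res % 32 != 0)
      Rcpp::stop("resolution must be a positive multiple of 32, got %d", res);
    s = res / 32;
    c32 = chan(32); c64 = chan(64); c128 = chan(128); c256 = chan(256);
    c512 = chan(512); latent = chan(256); c128r = chan(128);
    if (c512 % (s * s) != 0)
      Rcpp::stop("width %g incompatible with resolution %d: %d not divisible by %d",
                 width, res, c512, s * s);
    Crs = c512 / (s * s);
    for (int i = 0; i < 4; ++i) dc[i] = std::max(1, (int)dch[i]);
    seed_rngs(seed);

    const int ec_in[4]  = {1, c32, c64, c128};
    const int ec_out[4] = {c32, c64, c128, c256};
    int H = res;
    for (int i = 0; i < 4; ++i) {
      for (int t = 0; t < 2; ++t) {
        ConvSpec& L = enc[t][i];
        L = {ec_in[i], ec_out[i], 5, 2, 2, H, H, H / 2, H / 2, nullptr, nullptr};
        char nm[32]; std::snprintf(nm, sizeof nm, "conv%d", i + 1);
        L.W = add(L.Cout, L.Cin * 25, t, std::string(nm) + ".W");
        L.b = add(L.Cout, 1, t, std::string(nm) + ".b");
      }
      H /= 2;
    }
    senc = {c256, c512, 5, 2, 2, H, H, H / 2, H / 2, nullptr, nullptr};
    senc.W = add(c512, c256 * 25, 2, "conv5.W");
    senc.b = add(c512, 1, 2, "conv5.b");

    fc1  = {c512 * s * s, c512, nullptr, nullptr};
    fc1.W  = add(c512, c512 * s * s, 3, "fc1.W");  fc1.b  = add(c512, 1, 3, "fc1.b");
    fcmu = {c512, latent, nullptr, nullptr};
    fcmu.W = add(latent, c512, 3, "fc_mean.W");    fcmu.b = add(latent, 1, 3, "fc_mean.b");
    fclv = {c512, latent, nullptr, nullptr};
    fclv.W = add(latent, c512, 3, "fc_logvar.W");  fclv.b = add(latent, 1, 3, "fc_logvar.b");
    fc2  = {latent, c512, nullptr, nullptr};
    fc2.W  = add(c512, latent, 3, "fc2.W");        fc2.b  = add(c512, 1, 3, "fc2.b");

    sdec = {Crs, c256, 5, 2, 2, 1, s, s, 2 * s, 2 * s, nullptr, nullptr};
    sdec.W = add(Crs, c256 * 25, 4, "convT0.W");
    sdec.b = add(c256, 1, 4, "convT0.b");
    bn_gamma = add(c256, 1, 4, "bn.gamma");
    bn_beta  = add(c256, 1, 4, "bn.beta");
    bn_gamma->W.ones();
    bn_rmean.zeros(c256); bn_rvar.ones(c256);

    const int dck[5]  = {5, 5, 5, 2, 6};
    const int dcs[5]  = {2, 2, 2, 1, 2};
    const int dcp[5]  = {2, 2, 2, 0, 3};
    const int dcop[5] = {1, 1, 1, 0, 0};
    const int dcin[5]  = {c256, dc[0], dc[1], dc[2], dc[3]};
    const int dcout[5] = {dc[0], dc[1], dc[2], dc[3], 1};
    const int dH[6] = {2 * s, 4 * s, 8 * s, 16 * s, 16 * s + 1, 32 * s};
    for (int i = 0; i < 5; ++i) {
      for (int t = 0; t < 2; ++t) {
        ConvTSpec& L = dec[t][i];
        L = {dcin[i], dcout[i], dck[i], dcs[i], dcp[i], dcop[i],
             dH[i], dH[i], dH[i + 1], dH[i + 1], nullptr, nullptr};
        char nm[32]; std::snprintf(nm, sizeof nm, "convT%d", i + 1);
        L.W = add(L.Cin, L.Cout * L.K * L.K, 5 + t, std::string(nm) + ".W");
        L.b = add(L.Cout, 1, 5 + t, std::string(nm) + ".b");
      }
    }
    rfc1 = {c256, c128r, nullptr, nullptr};
    rfc1.W = add(c128r, c256, 7, "fc1.W");  rfc1.b = add(c128r, 1, 7, "fc1.b");
    rfc2 = {c128r, 1, nullptr, nullptr};
    rfc2.W = add(1, c128r, 7, "fc2.W");     rfc2.b = add(1, 1, 7, "fc2.b");

    for (auto& p : params)
      if (p->name.size() > 2 && p->name.substr(p->name.size() - 2) == ".W")
        orth_init(p->W);
  }

  // elementwise helpers ----------------------------------------------------
  void lrelu(fmat& X) {
    float* p = X.memptr();
    const float sl = slope;
    for (arma::uword i = 0; i < X.n_elem; ++i)
      if (p[i] < 0.0f) p[i] *= sl;
  }
  static void lrelu_bwd(const fmat& Y, fmat& G, float sl) {
    const float* y = Y.memptr(); float* g = G.memptr();
    for (arma::uword i = 0; i < G.n_elem; ++i)
      if (y[i] < 0.0f) g[i] *= sl;
  }
  void make_mask(fmat& M, arma::uword nr, arma::uword nc) {
    M.set_size(nr, nc);
    const float keep = 1.0f - drop, inv = 1.0f / keep;
    const uint32_t thr = (uint32_t)(keep * 4294967296.0);
    float* p = M.memptr();
    for (arma::uword i = 0; i < M.n_elem; ++i)
      p[i] = (fast_rng.next() < thr) ? inv : 0.0f;
  }
  void normal_fill(fmat& E) {
    std::normal_distribution<double> nd(0.0, 1.0);
    float* p = E.memptr();
    for (arma::uword i = 0; i < E.n_elem; ++i) p[i] = (float)nd(rng);
  }

  // forward ----------------------------------------------------------------
  // x_nat / x_syn: (res*res, B_t).  Either may have zero columns.
  void forward(const fmat& x_nat, const fmat& x_syn, bool train, bool sample) {
    C = Cache();
    C.train = train;
    C.Bn = x_nat.n_cols; C.Bs = x_syn.n_cols;
    const int B = C.Bn + C.Bs;
    if (B == 0) Rcpp::stop("empty batch");
    const int HW = res * res;

    fmat E;                                     // concatenated encoder output
    for (int t = 0; t < 2; ++t) {
      const fmat& xt = (t == 0) ? x_nat : x_syn;
      const int Bt = (t == 0) ? C.Bn : C.Bs;
      if (Bt == 0) continue;
      C.xin[t] = fmat(const_cast<float*>(xt.memptr()), 1, (size_t)HW * Bt, true);
      fmat cur = C.xin[t];
      for (int i = 0; i < 4; ++i) {
        fmat Y;
        conv_fwd(enc[t][i], cur, Y, Bt, train ? &C.ecols[t][i] : nullptr);
        lrelu(Y);
        C.eact[t][i] = std::move(Y);
        if (train) {
          make_mask(C.emask[t][i], C.eact[t][i].n_rows, C.eact[t][i].n_cols);
          cur = C.eact[t][i] % C.emask[t][i];
        } else cur = C.eact[t][i];
      }
      E = (E.n_elem == 0) ? cur : fmat(arma::join_rows(E, cur));
    }

    fmat Y5;
    conv_fwd(senc, E, Y5, B, train ? &C.scols : nullptr);
    lrelu(Y5);
    C.sact = std::move(Y5);
    fmat scur;
    if (train) {
      make_mask(C.smask, C.sact.n_rows, C.sact.n_cols);
      scur = C.sact % C.smask;
    } else scur = C.sact;

    // flatten: (c512, s*s*B) memory == (c512*s*s, B)
    fmat flat(scur.memptr(), (size_t)c512 * s * s, B);

    fmat h = fc1.W->W * flat; h.each_col() += fc1.b->W.col(0);
    lrelu(h);
    C.h1 = std::move(h);
    fmat hdrop;
    if (train) { make_mask(C.m1, C.h1.n_rows, C.h1.n_cols); hdrop = C.h1 % C.m1; }
    else hdrop = C.h1;

    C.mu = fcmu.W->W * hdrop; C.mu.each_col() += fcmu.b->W.col(0);
    C.lv = fclv.W->W * hdrop; C.lv.each_col() += fclv.b->W.col(0);
    C.lv = arma::clamp(C.lv, -15.0f, 15.0f);
    if (sample) {
      C.eps.set_size(latent, B);
      normal_fill(C.eps);
      C.z = C.mu + arma::exp(0.5f * C.lv) % C.eps;
    } else C.z = C.mu;

    fmat g2 = fc2.W->W * C.z; g2.each_col() += fc2.b->W.col(0);
    lrelu(g2);
    C.h2 = std::move(g2);
    fmat gdrop;
    if (train) { make_mask(C.m2, C.h2.n_rows, C.h2.n_cols); gdrop = C.h2 % C.m2; }
    else gdrop = C.h2;

    C.sd_in = fmat(gdrop.memptr(), Crs, (size_t)s * s * B);  // un-flatten
    fmat D;
    convT_fwd(sdec, C.sd_in, D, B);

    // batch norm over channels
    {
      const arma::uword N = D.n_cols;
      if (train) {
        fvec mean = arma::mean(D, 1);
        fvec var = arma::var(D, 1, 1);          // biased
        C.bn_invstd = 1.0f / arma::sqrt(var + bn_eps);
        D.each_col() -= mean;
        D.each_col() %= C.bn_invstd;
        C.bn_xhat = D;
        const float unb = (N > 1) ? (float)N / (N - 1) : 1.0f;
        bn_rmean = (1.0f - bn_mom) * bn_rmean + bn_mom * mean;
        bn_rvar  = (1.0f - bn_mom) * bn_rvar  + bn_mom * (var * unb);
      } else {
        D.each_col() -= bn_rmean;
        D.each_col() %= fvec(1.0f / arma::sqrt(bn_rvar + bn_eps));
      }
      D.each_col() %= bn_gamma->W.col(0);
      D.each_col() += bn_beta->W.col(0);
    }
    lrelu(D);
    C.D = std::move(D);

    // regressor: global average pool over the (2s)^2 spatial columns
    const int sp = 4 * s * s;
    C.pooled.set_size(c256, B);
    for (int b = 0; b < B; ++b)
      C.pooled.col(b) = arma::mean(C.D.cols((size_t)b * sp, (size_t)(b + 1) * sp - 1), 1);
    fmat r1 = rfc1.W->W * C.pooled; r1.each_col() += rfc1.b->W.col(0);
    C.r1 = std::move(r1);
    fmat r1d;
    if (train) { make_mask(C.rmask, C.r1.n_rows, C.r1.n_cols); r1d = C.r1 % C.rmask; }
    else r1d = C.r1;
    C.r = rfc2.W->W * r1d; C.r.each_col() += rfc2.b->W.col(0);

    // outer decoders on the modality-specific column blocks
    for (int t = 0; t < 2; ++t) {
      const int Bt = (t == 0) ? C.Bn : C.Bs;
      if (Bt == 0) continue;
      const size_t off = (t == 0) ? 0 : (size_t)C.Bn * sp;
      fmat cur = C.D.cols(off, off + (size_t)Bt * sp - 1);
      for (int i = 0; i < 5; ++i) {
        fmat Y;
        convT_fwd(dec[t][i], cur, Y, Bt);
        if (i < 4) lrelu(Y);
        else Y = 1.0f / (1.0f + arma::exp(-Y));  // sigmoid
        C.dact[t][i] = std::move(Y);
        cur = C.dact[t][i];
      }
    }
  }

  // decode-only path (latent -> raster), evaluation mode
  fmat decode(const fmat& z, int t) {
    const int B = z.n_cols;
    fmat g2 = fc2.W->W * z; g2.each_col() += fc2.b->W.col(0);
    lrelu(g2);
    fmat sd_in(g2.memptr(), Crs, (size_t)s * s * B);
    fmat D;
    convT_fwd(sdec, sd_in, D, B);
    D.each_col() -= bn_rmean;
    D.each_col() %= fvec(1.0f / arma::sqrt(bn_rvar + bn_eps));
    D.each_col() %= bn_gamma->W.col(0);
    D.each_col() += bn_beta->W.col(0);
    lrelu(D);
    fmat cur = D;
    for (int i = 0; i < 5; ++i) {
      fmat Y;
      convT_fwd(dec[t][i], cur, Y, B);
      if (i < 4) lrelu(Y); else Y = 1.0f / (1.0f + arma::exp(-Y));
      cur = Y;
    }
    return fmat(cur.memptr(), (size_t)res * res, B);
  }

  // backward ---------------------------------------------------------------
  // d_recon[t]: (1, HW*Bt) gradients w.r.t. the sigmoid outputs;
  // d_r: (1, B); d_mu_extra/d_lv_extra: KL gradients (latent, B).
  void backward(fmat d_recon[2], const fmat& d_r,
                const fmat& d_mu_extra, const fmat& d_lv_extra) {
    const int B = C.Bn + C.Bs;
    const int sp = 4 * s * s;
    fmat dD(c256, (size_t)sp * B, arma::fill::zeros);

    for (int t = 0; t < 2; ++t) {
      const int Bt = (t == 0) ? C.Bn : C.Bs;
      if (Bt == 0 || d_recon[t].n_elem == 0) continue;
      fmat g = d_recon[t] % C.dact[t][4] % (1.0f - C.dact[t][4]);  // sigmoid
      for (int i = 4; i >= 0; --i) {
        const size_t off = (t == 0) ? 0 : (size_t)C.Bn * sp;
        const fmat& X = (i == 0)
          ? fmat(C.D.cols(off, off + (size_t)Bt * sp - 1))
          : C.dact[t][i - 1];
        fmat dX;
        convT_bwd(dec[t][i], X, g, dX, Bt);
        if (i > 0) lrelu_bwd(C.dact[t][i - 1], dX, slope);
        g = std::move(dX);
      }
      const size_t off = (t == 0) ? 0 : (size_t)C.Bn * sp;
      dD.cols(off, off + (size_t)Bt * sp - 1) += g;
    }

    // regressor branch
    if (d_r.n_elem > 0) {
      fmat r1d = C.train ? fmat(C.r1 % C.rmask) : C.r1;
      rfc2.W->g += d_r * r1d.t();
      rfc2.b->g.col(0) += arma::sum(d_r, 1);
      fmat dr1 = rfc2.W->W.t() * d_r;
      if (C.train) dr1 %= C.rmask;
      rfc1.W->g += dr1 * C.pooled.t();
      rfc1.b->g.col(0) += arma::sum(dr1, 1);
      fmat dpooled = rfc1.W->W.t() * dr1;
      dpooled /= (float)sp;
      for (int b = 0; b < B; ++b)
        dD.cols((size_t)b * sp, (size_t)(b + 1) * sp - 1).each_col() += dpooled.col(b);
    }

    lrelu_bwd(C.D, dD, slope);
    // batch-norm backward
    {
      const float N = (float)dD.n_cols;
      fvec dgamma = arma::sum(dD % C.bn_xhat, 1);
      fvec dbeta = arma::sum(dD, 1);
      bn_gamma->g.col(0) += dgamma;
      bn_beta->g.col(0) += dbeta;
      dD.each_col() %= bn_gamma->W.col(0);     // now d xhat
      fvec sum_dx = arma::sum(dD, 1);
      fvec sum_dxx = arma::sum(dD % C.bn_xhat, 1);
      fmat tmp = C.bn_xhat;
      tmp.each_col() %= sum_dxx;
      dD = dD * N;
      dD.each_col() -= sum_dx;
      dD -= tmp;
      dD.each_col() %= (C.bn_invstd / N);
    }

    fmat d_sd_in;
    convT_bwd(sdec, C.sd_in, dD, d_sd_in, B);
    fmat dg(d_sd_in.memptr(), c512, B);        // re-flatten
    if (C.train) dg %= C.m2;
    lrelu_bwd(C.h2, dg, slope);
    fmat h2in = C.z;
    fc2.W->g += dg * h2in.t();
    fc2.b->g.col(0) += arma::sum(dg, 1);
    fmat dz = fc2.W->W.t() * dg;

    fmat dmu = dz + d_mu_extra;
    fmat dlv = d_lv_extra;
    if (C.eps.n_elem > 0)
      dlv += dz % C.eps % (0.5f * arma::exp(0.5f * C.lv));

    fmat hdrop = C.train ? fmat(C.h1 % C.m1) : C.h1;
    fcmu.W->g += dmu * hdrop.t();
    fcmu.b->g.col(0) += arma::sum(dmu, 1);
    fclv.W->g += dlv * hdrop.t();
    fclv.b->g.col(0) += arma::sum(dlv, 1);
    fmat dh = fcmu.W->W.t() * dmu + fclv.W->W.t() * dlv;
    if (C.train) dh %= C.m1;
    lrelu_bwd(C.h1, dh, slope);

    fmat scur = C.train ? fmat(C.sact % C.smask) : C.sact;
    fmat flat(scur.memptr(), (size_t)c512 * s * s, B);
    fc1.W->g += dh * flat.t();
    fc1.b->g.col(0) += arma::sum(dh, 1);
    fmat dflat = fc1.W->W.t() * dh;
    fmat ds(dflat.memptr(), c512, (size_t)s * s * B);
    if (C.train) ds %= C.smask;
    lrelu_bwd(C.sact, ds, slope);

    // rebuild shared-encoder input from cached per-modality activations
    fmat E;
    for (int t = 0; t < 2; ++t) {
      const int Bt = (t == 0) ? C.Bn : C.Bs;
      if (Bt == 0) continue;
      fmat cur = C.train ? fmat(C.eact[t][3] % C.emask[t][3]) : C.eact[t][3];
      E = (E.n_elem == 0) ? cur : fmat(arma::join_rows(E, cur));
    }
    fmat dE;
    conv_bwd(senc, C.train ? &C.scols : nullptr, E, ds, dE, B);

    const int spe = (res / 16) * (res / 16);   // spatial cols per sample at enc4 out
    for (int t = 0; t < 2; ++t) {
      const int Bt = (t == 0) ? C.Bn : C.Bs;
      if (Bt == 0) continue;
      const size_t off = (t == 0) ? 0 : (size_t)C.Bn * spe;
      fmat g = dE.cols(off, off + (size_t)Bt * spe - 1);
      for (int i = 3; i >= 0; --i) {
        if (C.train) g %= C.emask[t][i];
        lrelu_bwd(C.eact[t][i], g, slope);
        const fmat& X = (i == 0)
          ? C.xin[t]
          : (C.train ? fmat(C.eact[t][i - 1] % C.emask[t][i - 1]) : C.eact[t][i - 1]);
        fmat dX;
        conv_bwd(enc[t][i], C.train ? &C.ecols[t][i] : nullptr, X, g, dX,
                 Bt, i > 0);
        g = std::move(dX);
      }
    }
  }

  void zero_grads() { for (auto& p : params) p->g.zeros(); }

  // optimizer: 0 = Adam, 1 = RAdam; decoupled weight decay; frozen parts
  // (trainable[part] == false) are skipped entirely, including decay and
  // moment updates, so they stay bit-identical.
  void optim_step(double lr, double wd, int kind, double b1, double b2,
                  const std::vector<bool>& trainable) {
    step_count += 1;
    const double t = (double)step_count;
    const double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
    const float eps = 1e-8f;
    double rho_inf = 2.0 / (1.0 - b2) - 1.0;
    double rho_t = rho_inf - 2.0 * t * std::pow(b2, t) / bc2;
    double rect = 0.0;
    bool rectify = false;
    if (kind == 1 && rho_t > 4.0) {
      rectify = true;
      rect = std::sqrt(((rho_t - 4.0) * (rho_t - 2.0) * rho_inf) /
                       ((rho_inf - 4.0) * (rho_inf - 2.0) * rho_t));
    }
    for (auto& p : params) {
      if (!trainable[p->part]) continue;
      p->m = (float)b1 * p->m + (float)(1.0 - b1) * p->g;
      p->v = (float)b2 * p->v + (float)(1.0 - b2) * (p->g % p->g);
      fmat mhat = p->m / (float)bc1;
      if (kind == 0) {
        fmat vhat = p->v / (float)bc2;
        p->W -= (float)lr * (mhat / (arma::sqrt(vhat) + eps));
      } else if (rectify) {
        fmat vhat = arma::sqrt(p->v / (float)bc2);
        p->W -= (float)(lr * rect) * (mhat / (vhat + eps));
      } else {
        p->W -= (float)lr * mhat;
      }
      if (wd > 0.0) p->W -= (float)(lr * wd) * p->W;
    }
  }
};

static Engine* get_engine(SEXP ptr) {
  Rcpp::XPtr<Engine> xp(ptr);
  return xp.get();
}

// ---- exported interface --------------------------------------------------

// [[Rcpp::export]]
SEXP eng_new(int resolution, double width, Rcpp::IntegerVector dec_channels,
             double seed, double dropout, double leak) {
  Engine* e = new Engine();
  e->build(resolution, width, dec_channels, (uint64_t)seed, dropout, leak);
  Rcpp::XPtr<Engine> xp(e, true);
  return xp;
}

// [[Rcpp::export]]
List eng_info(SEXP ptr) {
  Engine* e = get_engine(ptr);
  size_t n = 0;
  for (auto& p : e->params) n += p->W.n_elem;
  return List::create(
    Rcpp::Named("resolution") = e->res, Rcpp::Named("width") = e->width,
    Rcpp::Named("latent_dim") = e->latent,
    Rcpp::Named("encoder_channels") = Rcpp::IntegerVector::create(
      e->c32, e->c64, e->c128, e->c256),
    Rcpp::Named("shared_channels") = e->c512,
    Rcpp::Named("decoder_channels") = Rcpp::IntegerVector::create(
      e->dc[0], e->dc[1], e->dc[2], e->dc[3]),
    Rcpp::Named("n_parameters") = (double)n,
    Rcpp::Named("step_count") = (double)e->step_count);
}

// [[Rcpp::export]]
void eng_set_seed(SEXP ptr, double seed) {
  get_engine(ptr)->seed_rngs((uint64_t)seed);
}

// [[Rcpp::export]]
List eng_get_state(SEXP ptr) {
  Engine* e = get_engine(ptr);
  // count tensors per part, then fill GC-protected lists in place
  std::vector<int> counts(N_PARTS, 0);
  for (auto& p : e->params) counts[p->part] += 1;
  counts[4] += 2;  // batch-norm running statistics
  List out(N_PARTS);
  std::vector<Rcpp::CharacterVector> nms(N_PARTS);
  for (int i = 0; i < N_PARTS; ++i) {
    out[i] = List(counts[i]);
    nms[i] = Rcpp::CharacterVector(counts[i]);
  }
  std::vector<int> at(N_PARTS, 0);
  for (auto& p : e->params) {
    List li = out[p->part];
    li[at[p->part]] = Rcpp::wrap(arma::conv_to<arma::mat>::from(p->W));
    nms[p->part][at[p->part]] = p->name;
    at[p->part] += 1;
  }
  {
    List sd = out[4];
    sd[at[4]] = Rcpp::wrap(arma::conv_to<arma::vec>::from(e->bn_rmean));
    nms[4][at[4]] = "bn.running_mean";
    sd[at[4] + 1] = Rcpp::wrap(arma::conv_to<arma::vec>::from(e->bn_rvar));
    nms[4][at[4] + 1] = "bn.running_var";
  }
  Rcpp::CharacterVector pn(N_PARTS);
  for (int i = 0; i < N_PARTS; ++i) {
    List li = out[i];
    li.attr("names") = nms[i];
    out[i] = li;
    pn[i] = PART_NAMES[i];
  }
  out.attr("names") = pn;
  return out;
}

// [[Rcpp::export]]
void eng_set_state(SEXP ptr, List state) {
  Engine* e = get_engine(ptr);
  for (auto& p : e->params) {
    List part = state[PART_NAMES[p->part]];
    arma::mat M = Rcpp::as<arma::mat>(part[p->name]);
    if (M.n_rows != p->W.n_rows || M.n_cols != p->W.n_cols)
      Rcpp::stop("checkpoint incompatible: %s/%s is %dx%d, expected %dx%d",
                 PART_NAMES[p->part], p->name.c_str(),
                 (int)M.n_rows, (int)M.n_cols, (int)p->W.n_rows, (int)p->W.n_cols);
    p->W = arma::conv_to<fmat>::from(M);
  }
  List sd = state["shared_decoder"];
  e->bn_rmean = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(sd["bn.running_mean"]));
  e->bn_rvar  = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(sd["bn.running_var"]));
}

// [[Rcpp::export]]
List eng_get_opt_state(SEXP ptr) {
  Engine* e = get_engine(ptr);
  List m(e->params.size()), v(e->params.size());
  Rcpp::CharacterVector nm(e->params.size());
  for (size_t i = 0; i < e->params.size(); ++i) {
    m[i] = Rcpp::wrap(arma::conv_to<arma::mat>::from(e->params[i]->m));
    v[i] = Rcpp::wrap(arma::conv_to<arma::mat>::from(e->params[i]->v));
    nm[i] = std::string(PART_NAMES[e->params[i]->part]) + "/" + e->params[i]->name;
  }
  m.attr("names") = nm; v.attr("names") = nm;
  return List::create(Rcpp::Named("step_count") = (double)e->step_count,
                      Rcpp::Named("m") = m, Rcpp::Named("v") = v);
}

// [[Rcpp::export]]
void eng_set_opt_state(SEXP ptr, List st) {
  Engine* e = get_engine(ptr);
  e->step_count = (long)Rcpp::as<double>(st["step_count"]);
  List m = st["m"], v = st["v"];
  for (auto& p : e->params) {
    std::string key = std::string(PART_NAMES[p->part]) + "/" + p->name;
    p->m = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(m[key]));
    p->v = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(v[key]));
  }
}

// [[Rcpp::export]]
List eng_forward(SEXP ptr, arma::mat x, int modality, bool train, bool sample) {
  Engine* e = get_engine(ptr);
  fmat xf = arma::conv_to<fmat>::from(x);
  fmat empty(e->res * e->res, 0);
  if (modality == 0) e->forward(xf, empty, train, sample);
  else e->forward(empty, xf, train, sample);
  const fmat& rec = e->C.dact[modality][4];
  fmat recm(const_cast<float*>(rec.memptr()), (size_t)e->res * e->res, x.n_cols);
  return List::create(
    Rcpp::Named("reconstruction") = Rcpp::wrap(arma::conv_to<arma::mat>::from(recm)),
    Rcpp::Named("count") = Rcpp::wrap(arma::conv_to<arma::rowvec>::from(e->C.r)),
    Rcpp::Named("mean") = Rcpp::wrap(arma::conv_to<arma::mat>::from(e->C.mu)),
    Rcpp::Named("logvar") = Rcpp::wrap(arma::conv_to<arma::mat>::from(e->C.lv)),
    Rcpp::Named("sample") = Rcpp::wrap(arma::conv_to<arma::mat>::from(e->C.z)));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix eng_decode(SEXP ptr, arma::mat z, int modality) {
  Engine* e = get_engine(ptr);
  if ((int)z.n_rows != e->latent)
    Rcpp::stop("latent has %d rows, expected %d", (int)z.n_rows, e->latent);
  fmat out = e->decode(arma::conv_to<fmat>::from(z), modality);
  return Rcpp::wrap(arma::conv_to<arma::mat>::from(out));
}

// One semi-supervised optimization step on a mixed batch.
// reg_w_*: per-sample regression weights (0 for unlabeled / delayed).
// rec_kind: 0 = mse, 1 = bce.  Returns loss components and predictions.
// [[Rcpp::export]]
List eng_train_batch(SEXP ptr,
                     arma::mat x_nat, arma::vec label_nat, arma::vec reg_w_nat,
                     arma::mat x_syn, arma::vec label_syn, arma::vec reg_w_syn,
                     double c_rec_nat, double c_rec_syn,
                     int rec_kind_nat, int rec_kind_syn,
                     double c_kl_nat, double c_kl_syn,
                     double lr, double wd, int optimizer,
                     double beta1, double beta2,
                     Rcpp::LogicalVector trainable, bool apply) {
  Engine* e = get_engine(ptr);
  const int Bn = x_nat.n_cols, Bs = x_syn.n_cols, B = Bn + Bs;
  const int P = e->res * e->res;
  if (B == 0) Rcpp::stop("empty batch");
  fmat xn = arma::conv_to<fmat>::from(x_nat);
  fmat xs = arma::conv_to<fmat>::from(x_syn);
  e->zero_grads();
  e->forward(xn, xs, true, true);

  const double c_rec[2] = {c_rec_nat, c_rec_syn};
  const int kind[2] = {rec_kind_nat, rec_kind_syn};
  const double c_kl[2] = {c_kl_nat, c_kl_syn};
  double rec_comp[2] = {0, 0}, kl_comp[2] = {0, 0};
  double reg_comp = 0.0, total = 0.0;
  int n_labeled = 0;

  // reconstruction losses and gradients
  fmat d_recon[2];
  for (int t = 0; t < 2; ++t) {
    const int Bt = (t == 0) ? Bn : Bs;
    if (Bt == 0) continue;
    const fmat& xorig = (t == 0) ? xn : xs;
    fmat xflat(const_cast<float*>(xorig.memptr()), 1, (size_t)P * Bt);
    const fmat& d = e->C.dact[t][4];
    double rec_sum = 0.0;
    d_recon[t].set_size(1, (size_t)P * Bt);
    const float* xp = xflat.memptr();
    const float* dp = d.memptr();
    float* gp = d_recon[t].memptr();
    const float scale = (float)(c_rec[t] / ((double)B * P));
    if (kind[t] == 0) {
      for (size_t i = 0; i < (size_t)P * Bt; ++i) {
        const float diff = dp[i] - xp[i];
        rec_sum += (double)diff * diff;
        gp[i] = scale * 2.0f * diff;
      }
    } else {
      const float lo = 1e-7f, hi = 1.0f - 1e-7f;
      for (size_t i = 0; i < (size_t)P * Bt; ++i) {
        float dd = dp[i] < lo ? lo : (dp[i] > hi ? hi : dp[i]);
        rec_sum += -((double)xp[i] * std::log((double)dd) +
                     (1.0 - xp[i]) * std::log(1.0 - (double)dd));
        gp[i] = scale * (dd - xp[i]) / (dd * (1.0f - dd));
      }
    }
    rec_comp[t] = rec_sum / ((double)Bt * P);       // per-sample mean Rec
    total += c_rec[t] * rec_sum / ((double)B * P);
  }

  // regression loss and gradient
  fmat d_r(1, B, arma::fill::zeros);
  for (int i = 0; i < B; ++i) {
    const bool nat = i < Bn;
    const double w = nat ? reg_w_nat(i) : reg_w_syn(i - Bn);
    const double l = nat ? label_nat(i) : label_syn(i - Bn);
    const double r = (double)e->C.r(0, i);
    if (w > 0.0) {
      const double err = r - l;
      reg_comp += err * err;
      n_labeled += 1;
      total += w * err * err / B;
      d_r(0, i) = (float)(2.0 * w * err / B);
    }
  }
  if (n_labeled > 0) reg_comp /= n_labeled;

  // KL divergence and gradients
  fmat d_mu(e->latent, B), d_lv(e->latent, B);
  for (int i = 0; i < B; ++i) {
    const int t = (i < Bn) ? 0 : 1;
    const float ck = (float)(c_kl[t] / B);
    double kls = 0.0;
    for (int j = 0; j < e->latent; ++j) {
      const float mu = e->C.mu(j, i), lv = e->C.lv(j, i);
      const float ev = std::exp(lv);
      kls += -0.5 * (1.0 + lv - (double)mu * mu - ev);
      d_mu(j, i) = ck * mu;
      d_lv(j, i) = ck * 0.5f * (ev - 1.0f);
    }
    kl_comp[t] += kls;
    total += c_kl[t] * kls / B;
  }
  if (Bn > 0) kl_comp[0] /= Bn;
  if (Bs > 0) kl_comp[1] /= Bs;

  e->backward(d_recon, d_r, d_mu, d_lv);

  Rcpp::NumericVector gnorm(N_PARTS);
  for (auto& p : e->params) gnorm[p->part] += arma::accu(p->g % p->g);
  for (int i = 0; i < N_PARTS; ++i) gnorm[i] = std::sqrt(gnorm[i]);

  if (apply) {
    std::vector<bool> tr(N_PARTS);
    for (int i = 0; i < N_PARTS; ++i) tr[i] = trainable[i];
    e->optim_step(lr, wd, optimizer, beta1, beta2, tr);
  }

  return List::create(
    Rcpp::Named("total") = total,
    Rcpp::Named("rec_natural") = rec_comp[0], Rcpp::Named("rec_synthetic") = rec_comp[1],
    Rcpp::Named("reg") = reg_comp,
    Rcpp::Named("kl_natural") = kl_comp[0], Rcpp::Named("kl_synthetic") = kl_comp[1],
    Rcpp::Named("n_labeled") = n_labeled,
    Rcpp::Named("grad_norms") = gnorm,
    Rcpp::Named("predictions") = Rcpp::wrap(arma::conv_to<arma::rowvec>::from(e->C.r)));
}

// [[Rcpp::export]]
List eng_get_grads(SEXP ptr) {
  Engine* e = get_engine(ptr);
  List out(e->params.size());
  Rcpp::CharacterVector nm(e->params.size());
  for (size_t i = 0; i < e->params.size(); ++i) {
    out[i] = Rcpp::wrap(arma::conv_to<arma::mat>::from(e->params[i]->g));
    nm[i] = std::string(PART_NAMES[e->params[i]->part]) + "/" + e->params[i]->name;
  }
  out.attr("names") = nm;
  return out;
}

// Test hook: set every gradient to one and apply an optimizer step under the
// given trainable mask (used to verify the freeze contract exactly).
// [[Rcpp::export]]
void eng_ones_step(SEXP ptr, double lr, double wd, int optimizer,
                   double beta1, double beta2, Rcpp::LogicalVector trainable) {
  Engine* e = get_engine(ptr);
  for (auto& p : e->params) p->g.ones();
  std::vector<bool> tr(N_PARTS);
  for (int i = 0; i < N_PARTS; ++i) tr[i] = trainable[i];
  e->optim_step(lr, wd, optimizer, beta1, beta2, tr);
}

// [[Rcpp::export]]
Rcpp::CharacterVector eng_part_names() {
  Rcpp::CharacterVector out(N_PARTS);
  for (int i = 0; i < N_PARTS; ++i) out[i] = PART_NAMES[i];
  return out;
}
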