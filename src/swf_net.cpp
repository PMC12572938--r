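// Spiking wavelet transformer: training engine.
//
// All feature tensors are arma::mat with rows = (t, b, pixel) in t-major
// order (time step outermost, then batch item, then pixel in column-major
// image order) and columns = feature channels. LIF layers iterate over the
// T leading row-blocks and carry membrane state across them; every other
// layer treats rows independently, so batch/time flattening is exact.
//
// Backward passes implement backpropagation-through-time with the sigmoid
// surrogate gradient at each Heaviside and a detached hard reset. In
// "relaxed" mode the spike function becomes a sharpened sigmoid in the
// forward pass as well and the reset is differentiated exactly, which makes
// the whole network smooth -- used by finite-difference gradient checks.

#include <RcppArmadillo.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pin the loaded BLAS to a fixed thread count (no-op if the symbol is
// absent). Called at package load for serial, reproducible linear algebra.
// [[Rcpp::export]]
void cpp_set_blas_threads(int n) {
#ifndef _WIN32
  typedef void (*set_fn)(int);
  set_fn f = (set_fn)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f) f(n);
#endif
}
using arma::mat;
using arma::rowvec;
using arma::vec;
using arma::uword;

struct LifCfg {
  double tau, v_th, v_reset, alpha;
};

struct NetCfg {
  int T, d, L, pg, mlp_ratio, n_classes, heads, in_ch, map_hw;
  double scale_s, bn_momentum, bn_eps;
  bool wavelet_enabled, include_hh, relaxed, training;
  LifCfg lif;
};

static double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// ---------------------------------------------------------------- BN ----
struct BNCache {
  mat xhat;
  rowvec invstd;
  bool training;
};

struct BNParam {
  rowvec gamma, beta;
  rowvec run_m, run_v;   // running stats (updated in training mode)
  rowvec dgamma, dbeta;
};

static mat bn_forward(const mat& X, BNParam& p, BNCache& c, const NetCfg& cfg) {
  const double eps = cfg.bn_eps;
  c.training = cfg.training;
  if (cfg.training) {
    rowvec mu = arma::mean(X, 0);
    rowvec var = arma::mean(arma::square(X.each_row() - mu), 0);
    c.invstd = 1.0 / arma::sqrt(var + eps);
    c.xhat = (X.each_row() - mu).each_row() % c.invstd;
    p.run_m = (1 - cfg.bn_momentum) * p.run_m + cfg.bn_momentum * mu;
    p.run_v = (1 - cfg.bn_momentum) * p.run_v + cfg.bn_momentum * var;
    return (c.xhat.each_row() % p.gamma).each_row() + p.beta;
  }
  rowvec invstd = 1.0 / arma::sqrt(p.run_v + eps);
  mat xhat = (X.each_row() - p.run_m).each_row() % invstd;
  return (xhat.each_row() % p.gamma).each_row() + p.beta;
}

static mat bn_backward(const mat& dY, BNParam& p, const BNCache& c) {
  p.dgamma = arma::sum(dY % c.xhat, 0);
  p.dbeta = arma::sum(dY, 0);
  const double N = (double)dY.n_rows;
  mat dxhat = dY.each_row() % p.gamma;
  rowvec s1 = arma::sum(dxhat, 0);
  rowvec s2 = arma::sum(dxhat % c.xhat, 0);
  mat dX = dxhat * N;
  dX.each_row() -= s1;
  dX -= c.xhat.each_row() % s2;
  dX.each_row() %= (c.invstd / N);
  return dX;
}

// --------------------------------------------------------------- LIF ----
struct LifCache {
  mat H, S;
};

static mat lif_forward(const mat& X, int T, const NetCfg& cfg, LifCache& c) {
  const LifCfg& l = cfg.lif;
  const uword RB = X.n_rows / T;
  c.H.set_size(X.n_rows, X.n_cols);
  c.S.set_size(X.n_rows, X.n_cols);
  mat V(RB, X.n_cols, arma::fill::zeros);  // initial membrane potential 0
  for (int t = 0; t < T; ++t) {
    const uword r0 = (uword)t * RB;
    mat H = V + (X.rows(r0, r0 + RB - 1) - (V - l.v_reset)) / l.tau;
    mat S(RB, X.n_cols);
    if (cfg.relaxed) {
      S = 1.0 / (1.0 + arma::exp(-l.alpha * (H - l.v_th)));
    } else {
      S = arma::conv_to<mat>::from(H - l.v_th >= 0.0);
    }
    V = H % (1.0 - S) + l.v_reset * S;
    c.H.rows(r0, r0 + RB - 1) = H;
    c.S.rows(r0, r0 + RB - 1) = S;
  }
  return c.S;
}

static mat lif_backward(const mat& dS, int T, const NetCfg& cfg,
                        const LifCache& c) {
  const LifCfg& l = cfg.lif;
  const uword RB = dS.n_rows / T;
  mat dX(dS.n_rows, dS.n_cols);
  mat gV(RB, dS.n_cols, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const uword r0 = (uword)t * RB;
    mat H = c.H.rows(r0, r0 + RB - 1);
    mat S = c.S.rows(r0, r0 + RB - 1);
    mat sg = 1.0 / (1.0 + arma::exp(-l.alpha * (H - l.v_th)));
    mat surr = l.alpha * sg % (1.0 - sg);
    mat gH;
    if (cfg.relaxed) {
      // exact gradient of the smooth forward (reset differentiated)
      gH = (dS.rows(r0, r0 + RB - 1) - gV % (H - l.v_reset)) % surr +
           gV % (1.0 - S);
    } else {
      // surrogate at the Heaviside, detached reset
      gH = dS.rows(r0, r0 + RB - 1) % surr + gV % (1.0 - S);
    }
    dX.rows(r0, r0 + RB - 1) = gH / l.tau;
    gV = gH * (1.0 - 1.0 / l.tau);
  }
  return dX;
}

// -------------------------------------------------------------- conv ----
// 3x3 same-padded convolution via im2col. Image pixels are in column-major
// order (y fastest) within each sample block of H*W rows. Weight matrix is
// (9*cin) x cout with patch column index ky + 3*kx + 9*ci, matching the
// column-major flattening of an R array dim c(3, 3, cin, cout).
struct ConvCache {
  mat patches;
  int H, W, cin;
};

static mat conv_im2col(const mat& X, int H, int W, int n_samp) {
  const int cin = X.n_cols;
  const int P = H * W;
  mat patches(X.n_rows, 9 * cin, arma::fill::zeros);
  for (int s = 0; s < n_samp; ++s) {
    const uword base = (uword)s * P;
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = ky - 1, dx = kx - 1;
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= H * 0 + W) continue;
          const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
          if (y1 <= y0) continue;
          for (int ci = 0; ci < cin; ++ci) {
            const int pc = ky + 3 * kx + 9 * ci;
            for (int y = y0; y < y1; ++y) {
              patches(base + (uword)(x * H + y), pc) =
                  X(base + (uword)(sx * H + y + dy), ci);
            }
          }
        }
      }
    }
  }
  return patches;
}

static mat conv_forward(const mat& X, const mat& Wm, int H, int W,
                        int n_samp, ConvCache& c) {
  c.patches = conv_im2col(X, H, W, n_samp);
  c.H = H; c.W = W; c.cin = X.n_cols;
  return c.patches * Wm;
}

static mat conv_backward(const mat& dY, const mat& Wm, const ConvCache& c,
                         int n_samp, mat& dWm, bool need_dx = true) {
  dWm = c.patches.t() * dY;
  if (!need_dx) return mat();
  mat dP = dY * Wm.t();
  const int H = c.H, W = c.W, cin = c.cin, P = H * W;
  mat dX(dY.n_rows, cin, arma::fill::zeros);
  for (int s = 0; s < n_samp; ++s) {
    const uword base = (uword)s * P;
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = ky - 1, dx = kx - 1;
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
          for (int ci = 0; ci < cin; ++ci) {
            const int pc = ky + 3 * kx + 9 * ci;
            for (int y = y0; y < y1; ++y) {
              dX(base + (uword)(sx * H + y + dy), ci) +=
                  dP(base + (uword)(x * H + y), pc);
            }
          }
        }
      }
    }
  }
  return dX;
}

// -------------------------------------------------------------- pool ----
struct PoolCache {
  arma::umat src;  // chosen input row per output element
};

static mat pool_forward(const mat& X, int H, int W, int n_samp, PoolCache& c) {
  const int Ho = H / 2, Wo = W / 2, P = H * W, Po = Ho * Wo;
  const int C = X.n_cols;
  mat Y((uword)n_samp * Po, C);
  c.src.set_size((uword)n_samp * Po, C);
  for (int s = 0; s < n_samp; ++s) {
    const uword bi = (uword)s * P, bo = (uword)s * Po;
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        const uword out = bo + (uword)(xo * Ho + yo);
        const uword cand[4] = {
          bi + (uword)((2 * xo) * H + 2 * yo),
          bi + (uword)((2 * xo) * H + 2 * yo + 1),
          bi + (uword)((2 * xo + 1) * H + 2 * yo),
          bi + (uword)((2 * xo + 1) * H + 2 * yo + 1)};
        for (int ch = 0; ch < C; ++ch) {
          double best = X(cand[0], ch);
          uword bidx = cand[0];
          for (int k = 1; k < 4; ++k) {
            if (X(cand[k], ch) > best) { best = X(cand[k], ch); bidx = cand[k]; }
          }
          Y(out, ch) = best;
          c.src(out, ch) = bidx;
        }
      }
    }
  }
  return Y;
}

static mat pool_backward(const mat& dY, const PoolCache& c, uword n_rows_in) {
  mat dX(n_rows_in, dY.n_cols, arma::fill::zeros);
  for (uword i = 0; i < dY.n_rows; ++i) {
    for (uword ch = 0; ch < dY.n_cols; ++ch) {
      dX(c.src(i, ch), ch) += dY(i, ch);
    }
  }
  return dX;
}

// -------------------------------------------------------------- haar ----
// Single-level orthonormal 2D Haar on the g x g token grid (column-major
// pixel order). Analysis maps each sample's g*g rows to (g/2)^2 rows with
// channel-wise concatenated sub-bands [LL | LH | HL | (HH)]; synthesis
// inverts from four d-column groups. Orthonormality makes the Jacobian of
// analysis the transpose of synthesis, so each is the other's backward.

struct HaarIdx {
  arma::uvec a, b, c, d;  // within-sample corner pixel indices
  int g, q;               // grid side, q = (g/2)^2
};

static HaarIdx haar_idx(int g) {
  HaarIdx h;
  h.g = g;
  const int go = g / 2;
  h.q = go * go;
  h.a.set_size(h.q); h.b.set_size(h.q); h.c.set_size(h.q); h.d.set_size(h.q);
  for (int xo = 0; xo < go; ++xo) {
    for (int yo = 0; yo < go; ++yo) {
      const int o = xo * go + yo;
      const int y = 2 * yo, x = 2 * xo;
      h.a(o) = (uword)(x * g + y);            // (row y,   col x)
      h.b(o) = (uword)((x + 1) * g + y);      // (row y,   col x+1)
      h.c(o) = (uword)(x * g + y + 1);        // (row y+1, col x)
      h.d(o) = (uword)((x + 1) * g + y + 1);  // (row y+1, col x+1)
    }
  }
  return h;
}

// X: (n_samp * g*g) x d -> (n_samp * q) x (3d or 4d)
static mat haar_analyze(const mat& X, const HaarIdx& h, int n_samp,
                        bool include_hh) {
  const int d = X.n_cols, P = h.g * h.g;
  const int nb = include_hh ? 4 : 3;
  mat Y((uword)n_samp * h.q, (uword)nb * d);
  for (int s = 0; s < n_samp; ++s) {
    const uword bi = (uword)s * P, bo = (uword)s * h.q;
    for (int o = 0; o < h.q; ++o) {
      for (int ch = 0; ch < d; ++ch) {
        const double a = X(bi + h.a(o), ch), b = X(bi + h.b(o), ch);
        const double cc = X(bi + h.c(o), ch), dd = X(bi + h.d(o), ch);
        Y(bo + o, ch) = (a + b + cc + dd) / 2.0;                 // LL
        Y(bo + o, d + ch) = (a - b + cc - dd) / 2.0;             // LH
        Y(bo + o, 2 * d + ch) = (a + b - cc - dd) / 2.0;         // HL
        if (include_hh) Y(bo + o, 3 * d + ch) = (a - b - cc + dd) / 2.0;
      }
    }
  }
  return Y;
}

// adjoint of haar_analyze (scatter the sub-band gradients back)
static mat haar_analyze_bwd(const mat& dY, const HaarIdx& h, int n_samp,
                            bool include_hh, int d) {
  const int P = h.g * h.g;
  mat dX((uword)n_samp * P, d, arma::fill::zeros);
  for (int s = 0; s < n_samp; ++s) {
    const uword bi = (uword)s * P, bo = (uword)s * h.q;
    for (int o = 0; o < h.q; ++o) {
      for (int ch = 0; ch < d; ++ch) {
        const double ll = dY(bo + o, ch), lh = dY(bo + o, d + ch);
        const double hl = dY(bo + o, 2 * d + ch);
        const double hh = include_hh ? dY(bo + o, 3 * d + ch) : 0.0;
        dX(bi + h.a(o), ch) += (ll + lh + hl + hh) / 2.0;
        dX(bi + h.b(o), ch) += (ll - lh + hl - hh) / 2.0;
        dX(bi + h.c(o), ch) += (ll + lh - hl - hh) / 2.0;
        dX(bi + h.d(o), ch) += (ll - lh - hl + hh) / 2.0;
      }
    }
  }
  return dX;
}

// S: (n_samp * q) x 4d spike sub-bands -> (n_samp * g*g) x d reconstruction
static mat haar_synthesize(const mat& S, const HaarIdx& h, int n_samp, int d) {
  const int P = h.g * h.g;
  mat X((uword)n_samp * P, d);
  for (int s = 0; s < n_samp; ++s) {
    const uword bi = (uword)s * P, bo = (uword)s * h.q;
    for (int o = 0; o < h.q; ++o) {
      for (int ch = 0; ch < d; ++ch) {
        const double ll = S(bo + o, ch), lh = S(bo + o, d + ch);
        const double hl = S(bo + o, 2 * d + ch), hh = S(bo + o, 3 * d + ch);
        X(bi + h.a(o), ch) = (ll + lh + hl + hh) / 2.0;
        X(bi + h.b(o), ch) = (ll - lh + hl - hh) / 2.0;
        X(bi + h.c(o), ch) = (ll + lh - hl - hh) / 2.0;
        X(bi + h.d(o), ch) = (ll - lh - hl + hh) / 2.0;
      }
    }
  }
  return X;
}

// adjoint of haar_synthesize
static mat haar_synthesize_bwd(const mat& dX, const HaarIdx& h, int n_samp,
                               int d) {
  const int P = h.g * h.g;
  mat dS((uword)n_samp * h.q, 4 * d);
  for (int s = 0; s < n_samp; ++s) {
    const uword bi = (uword)s * P, bo = (uword)s * h.q;
    for (int o = 0; o < h.q; ++o) {
      for (int ch = 0; ch < d; ++ch) {
        const double a = dX(bi + h.a(o), ch), b = dX(bi + h.b(o), ch);
        const double cc = dX(bi + h.c(o), ch), dd = dX(bi + h.d(o), ch);
        dS(bo + o, ch) = (a + b + cc + dd) / 2.0;
        dS(bo + o, d + ch) = (a - b + cc - dd) / 2.0;
        dS(bo + o, 2 * d + ch) = (a + b - cc - dd) / 2.0;
        dS(bo + o, 3 * d + ch) = (a - b - cc + dd) / 2.0;
      }
    }
  }
  return dS;
}

// --------------------------------------------------------- attention ----
// Per (t, b) sample and head: A = s * (Q K^T) V. No softmax anywhere.
struct AttnCache {
  mat Q, K, V;
};

static mat attn_core_forward(const mat& Q, const mat& K, const mat& V,
                             const NetCfg& cfg, int n_samp, int N,
                             AttnCache& c) {
  c.Q = Q; c.K = K; c.V = V;
  const int dh = cfg.d / cfg.heads;
  mat A(Q.n_rows, Q.n_cols);
  for (int s = 0; s < n_samp; ++s) {
    const uword r0 = (uword)s * N, r1 = r0 + N - 1;
    for (int hh = 0; hh < cfg.heads; ++hh) {
      const uword c0 = (uword)hh * dh, c1 = c0 + dh - 1;
      mat Qh = Q.submat(r0, c0, r1, c1);
      mat Kh = K.submat(r0, c0, r1, c1);
      mat Vh = V.submat(r0, c0, r1, c1);
      A.submat(r0, c0, r1, c1) = cfg.scale_s * (Qh * Kh.t()) * Vh;
    }
  }
  return A;
}

static void attn_core_backward(const mat& dA, const NetCfg& cfg, int n_samp,
                               int N, const AttnCache& c, mat& dQ, mat& dK,
                               mat& dV) {
  const int dh = cfg.d / cfg.heads;
  dQ.set_size(dA.n_rows, dA.n_cols);
  dK.set_size(dA.n_rows, dA.n_cols);
  dV.set_size(dA.n_rows, dA.n_cols);
  for (int s = 0; s < n_samp; ++s) {
    const uword r0 = (uword)s * N, r1 = r0 + N - 1;
    for (int hh = 0; hh < cfg.heads; ++hh) {
      const uword c0 = (uword)hh * dh, c1 = c0 + dh - 1;
      mat Qh = c.Q.submat(r0, c0, r1, c1);
      mat Kh = c.K.submat(r0, c0, r1, c1);
      mat Vh = c.V.submat(r0, c0, r1, c1);
      mat dAh = cfg.scale_s * dA.submat(r0, c0, r1, c1);
      mat P = Qh * Kh.t();
      dV.submat(r0, c0, r1, c1) = P.t() * dAh;
      mat dP = dAh * Vh.t();
      dQ.submat(r0, c0, r1, c1) = dP * Kh;
      dK.submat(r0, c0, r1, c1) = dP.t() * Qh;
    }
  }
}

// ------------------------------------------------------------ params ----
struct LinParam {
  mat W, dW;
};

struct ConvParam {
  mat W, dW;  // (9*cin) x cout
};

struct Block {
  LinParam wq, wk, wv, wo, wf, w1, w2;
  BNParam bnq, bnk, bnv, bno, bnw, bnf, bn1, bn2;
  ConvParam wav;
};

struct Net {
  std::vector<ConvParam> sps_conv;
  std::vector<BNParam> sps_bn;
  std::vector<Block> blocks;
  LinParam head;
  vec head_b, dhead_b;
};

static rowvec get_rowvec(List p, const std::string& nm) {
  NumericVector v = p[nm];
  return rowvec(v.begin(), v.size());
}

static mat get_mat(List p, const std::string& nm) {
  NumericVector v = p[nm];
  if (v.hasAttribute("dim")) {
    IntegerVector d = v.attr("dim");
    if (d.size() == 2) return mat(v.begin(), d[0], d[1]);
    if (d.size() == 4) return mat(v.begin(), d[0] * d[1] * d[2], d[3]);
  }
  return mat(v.begin(), v.size(), 1);
}

static void get_bn(List p, List st, const std::string& nm, BNParam& b) {
  b.gamma = get_rowvec(p, nm + "_g");
  b.beta = get_rowvec(p, nm + "_b");
  b.run_m = get_rowvec(st, nm + "_m");
  b.run_v = get_rowvec(st, nm + "_v");
}

static int n_sps_stages(const NetCfg& cfg) {
  int s = 0, hw = cfg.map_hw;
  while (hw > cfg.pg) { hw /= 2; ++s; }
  return s;
}

static Net load_net(List params, List state, const NetCfg& cfg) {
  Net net;
  const int S = n_sps_stages(cfg);
  net.sps_conv.resize(S);
  net.sps_bn.resize(S);
  for (int i = 0; i < S; ++i) {
    std::string t = std::to_string(i + 1);
    net.sps_conv[i].W = get_mat(params, "sps_conv" + t);
    get_bn(params, state, "sps_bn" + t, net.sps_bn[i]);
  }
  net.blocks.resize(cfg.L);
  for (int l = 0; l < cfg.L; ++l) {
    std::string t = "blk" + std::to_string(l + 1) + "_";
    Block& b = net.blocks[l];
    b.wq.W = get_mat(params, t + "wq");
    b.wk.W = get_mat(params, t + "wk");
    b.wv.W = get_mat(params, t + "wv");
    b.wo.W = get_mat(params, t + "wo");
    get_bn(params, state, t + "bnq", b.bnq);
    get_bn(params, state, t + "bnk", b.bnk);
    get_bn(params, state, t + "bnv", b.bnv);
    get_bn(params, state, t + "bno", b.bno);
    if (cfg.wavelet_enabled) {
      b.wav.W = get_mat(params, t + "wav");
      get_bn(params, state, t + "bnw", b.bnw);
      b.wf.W = get_mat(params, t + "wf");
      get_bn(params, state, t + "bnf", b.bnf);
    }
    b.w1.W = get_mat(params, t + "w1");
    b.w2.W = get_mat(params, t + "w2");
    get_bn(params, state, t + "bn1", b.bn1);
    get_bn(params, state, t + "bn2", b.bn2);
  }
  net.head.W = get_mat(params, "head_W");
  NumericVector hb = params["head_b"];
  net.head_b = vec(hb.begin(), hb.size());
  return net;
}

// ----------------------------------------------------------- context ----
struct SpikeProbe {
  std::vector<std::string> names;
  std::vector<double> rates;
  std::vector<double> counts;
  std::vector<bool> binary;
  bool active = false;
  bool check_binary = true;
  void add(const std::string& nm, const mat& S) {
    if (!active) return;
    names.push_back(nm);
    rates.push_back(arma::accu(S) / (double)S.n_elem);
    counts.push_back((double)S.n_elem);
    bool bin = true;
    if (check_binary) {
      for (uword i = 0; i < S.n_elem && bin; ++i) {
        const double v = S(i);
        if (v != 0.0 && v != 1.0) bin = false;
      }
    }
    binary.push_back(bin);
  }
};

struct StageCtx {
  ConvCache conv;
  BNCache bn;
  LifCache lif;
  PoolCache pool;
  int H, W;
  uword rows_in;
};

struct BlockCtx {
  BNCache bnq, bnk, bnv, bno, bnw, bnf, bn1, bn2;
  LifCache lq, lk, lv, lattn, lo, lw, lf, l1, l2;
  AttnCache attn;
  ConvCache wconv;
  mat Xin, X1;        // residual stream snapshots
  mat attn_in_q, attn_in_k, attn_in_v;  // pre-BN linear outputs not needed; keep none
};

struct FwdCtx {
  std::vector<StageCtx> stages;
  std::vector<BlockCtx> blocks;
  mat Xtok;      // SPS output
  mat F;         // pooled features (B x d)
  mat logits;
  int B, N;
  HaarIdx haar;
};

// ----------------------------------------------------------- forward ----
static mat forward_pass(Net& net, const NetCfg& cfg, const mat& X0, int B,
                        FwdCtx& ctx, SpikeProbe& probe) {
  const int T = cfg.T;
  const int S = n_sps_stages(cfg);
  ctx.B = B;
  ctx.stages.resize(S);
  mat X = X0;
  int H = cfg.map_hw, W = cfg.map_hw;
  for (int i = 0; i < S; ++i) {
    StageCtx& st = ctx.stages[i];
    st.H = H; st.W = W;
    st.rows_in = X.n_rows;
    const int n_samp = T * B;
    mat Z = conv_forward(X, net.sps_conv[i].W, H, W, n_samp, st.conv);
    Z = bn_forward(Z, net.sps_bn[i], st.bn, cfg);
    mat Sp = lif_forward(Z, T, cfg, st.lif);
    probe.add("sps_lif" + std::to_string(i + 1), Sp);
    X = pool_forward(Sp, H, W, n_samp, st.pool);
    H /= 2; W /= 2;
  }
  ctx.Xtok = X;
  const int N = H * W;  // = pg^2 tokens
  ctx.N = N;
  ctx.haar = haar_idx(cfg.pg);
  const int n_samp = T * B;

  ctx.blocks.resize(cfg.L);
  for (int l = 0; l < cfg.L; ++l) {
    Block& b = net.blocks[l];
    BlockCtx& bc = ctx.blocks[l];
    bc.Xin = X;
    std::string t = "blk" + std::to_string(l + 1) + "_";

    mat Q = lif_forward(bn_forward(X * b.wq.W, b.bnq, bc.bnq, cfg), T, cfg, bc.lq);
    probe.add(t + "q", Q);
    mat K = lif_forward(bn_forward(X * b.wk.W, b.bnk, bc.bnk, cfg), T, cfg, bc.lk);
    probe.add(t + "k", K);
    mat V = lif_forward(bn_forward(X * b.wv.W, b.bnv, bc.bnv, cfg), T, cfg, bc.lv);
    probe.add(t + "v", V);
    mat A = attn_core_forward(Q, K, V, cfg, n_samp, N, bc.attn);
    mat Xattn = lif_forward(A, T, cfg, bc.lattn);
    probe.add(t + "attn", Xattn);
    mat Xo = lif_forward(bn_forward(Xattn * b.wo.W, b.bno, bc.bno, cfg), T, cfg,
                         bc.lo);
    probe.add(t + "proj", Xo);

    mat Xswsa;
    if (cfg.wavelet_enabled) {
      mat Sub = haar_analyze(X, ctx.haar, n_samp, cfg.include_hh);
      const int gq = cfg.pg / 2;
      mat Zw = conv_forward(Sub, b.wav.W, gq, gq, n_samp, bc.wconv);
      Zw = bn_forward(Zw, b.bnw, bc.bnw, cfg);
      mat Sw = lif_forward(Zw, T, cfg, bc.lw);
      probe.add(t + "wav", Sw);
      mat Xrec = haar_synthesize(Sw, ctx.haar, n_samp, cfg.d);
      mat Xcomb = arma::join_rows(Xo, Xrec);
      Xswsa = lif_forward(bn_forward(Xcomb * b.wf.W, b.bnf, bc.bnf, cfg), T,
                          cfg, bc.lf);
      probe.add(t + "fuse", Xswsa);
    } else {
      Xswsa = Xo;
    }
    mat X1 = X + Xswsa;
    bc.X1 = X1;
    mat Hm = lif_forward(bn_forward(X1 * b.w1.W, b.bn1, bc.bn1, cfg), T, cfg,
                         bc.l1);
    probe.add(t + "mlp1", Hm);
    mat Xmlp = lif_forward(bn_forward(Hm * b.w2.W, b.bn2, bc.bn2, cfg), T, cfg,
                           bc.l2);
    probe.add(t + "mlp2", Xmlp);
    X = X1 + Xmlp;
  }

  // GAP over tokens, then mean over time steps, then linear head
  mat G(T * B, cfg.d);
  for (int s = 0; s < T * B; ++s) {
    G.row(s) = arma::mean(X.rows((uword)s * N, (uword)s * N + N - 1), 0);
  }
  mat F(B, cfg.d, arma::fill::zeros);
  for (int t = 0; t < T; ++t) F += G.rows((uword)t * B, (uword)t * B + B - 1);
  F /= (double)T;
  ctx.F = F;
  ctx.logits = F * net.head.W;
  ctx.logits.each_row() += net.head_b.t();
  return ctx.logits;
}

// ---------------------------------------------------------- backward ----
static void backward_pass(Net& net, const NetCfg& cfg, const mat& dlogits,
                          FwdCtx& ctx) {
  const int T = cfg.T, B = ctx.B, N = ctx.N;
  const int n_samp = T * B;
  net.head.dW = ctx.F.t() * dlogits;
  net.dhead_b = arma::sum(dlogits, 0).t();
  mat dF = dlogits * net.head.W.t();
  mat dX((uword)n_samp * N, cfg.d);
  for (int t = 0; t < T; ++t) {
    for (int b = 0; b < B; ++b) {
      const uword s = (uword)t * B + b;
      const rowvec g = dF.row(b) / (double)(T * N);
      for (int p = 0; p < N; ++p) dX.row(s * N + p) = g;
    }
  }

  for (int l = cfg.L - 1; l >= 0; --l) {
    Block& b = net.blocks[l];
    BlockCtx& bc = ctx.blocks[l];
    // X2 = X1 + Xmlp
    mat dXmlp = dX;
    mat dX1 = dX;
    mat dHm = bn_backward(lif_backward(dXmlp, T, cfg, bc.l2), b.bn2, bc.bn2);
    b.w2.dW = bc.l1.S.t() * dHm;
    mat dH1 = dHm * b.w2.W.t();
    mat dZ1 = bn_backward(lif_backward(dH1, T, cfg, bc.l1), b.bn1, bc.bn1);
    b.w1.dW = bc.X1.t() * dZ1;
    dX1 += dZ1 * b.w1.W.t();

    // X1 = Xin + Xswsa
    mat dXswsa = dX1;
    mat dXin = dX1;

    mat dXo;
    if (cfg.wavelet_enabled) {
      mat dZf = bn_backward(lif_backward(dXswsa, T, cfg, bc.lf), b.bnf, bc.bnf);
      mat Xcomb = arma::join_rows(bc.lo.S, haar_synthesize(bc.lw.S, ctx.haar,
                                                           n_samp, cfg.d));
      b.wf.dW = Xcomb.t() * dZf;
      mat dXcomb = dZf * b.wf.W.t();
      dXo = dXcomb.cols(0, cfg.d - 1);
      mat dXrec = dXcomb.cols(cfg.d, 2 * cfg.d - 1);
      mat dSw = haar_synthesize_bwd(dXrec, ctx.haar, n_samp, cfg.d);
      mat dZw = bn_backward(lif_backward(dSw, T, cfg, bc.lw), b.bnw, bc.bnw);
      const int gq = cfg.pg / 2;
      mat dSub = conv_backward(dZw, b.wav.W, bc.wconv, n_samp, b.wav.dW);
      dXin += haar_analyze_bwd(dSub, ctx.haar, n_samp, cfg.include_hh, cfg.d);
    } else {
      dXo = dXswsa;
    }

    mat dXattn = bn_backward(lif_backward(dXo, T, cfg, bc.lo), b.bno, bc.bno);
    b.wo.dW = bc.lattn.S.t() * dXattn;
    mat dA = lif_backward(dXattn * b.wo.W.t(), T, cfg, bc.lattn);
    mat dQ, dK, dV;
    attn_core_backward(dA, cfg, n_samp, N, bc.attn, dQ, dK, dV);
    mat dZq = bn_backward(lif_backward(dQ, T, cfg, bc.lq), b.bnq, bc.bnq);
    mat dZk = bn_backward(lif_backward(dK, T, cfg, bc.lk), b.bnk, bc.bnk);
    mat dZv = bn_backward(lif_backward(dV, T, cfg, bc.lv), b.bnv, bc.bnv);
    b.wq.dW = bc.Xin.t() * dZq;
    b.wk.dW = bc.Xin.t() * dZk;
    b.wv.dW = bc.Xin.t() * dZv;
    dXin += dZq * b.wq.W.t() + dZk * b.wk.W.t() + dZv * b.wv.W.t();
    dX = dXin;
  }

  // SPS backward
  const int S = n_sps_stages(cfg);
  for (int i = S - 1; i >= 0; --i) {
    StageCtx& st = ctx.stages[i];
    const int n_s = T * B;
    mat dSp = pool_backward(dX, st.pool, st.rows_in);
    mat dZ = bn_backward(lif_backward(dSp, T, cfg, st.lif), net.sps_bn[i],
                         st.bn);
    // the first stage's input gradient is never consumed
    dX = conv_backward(dZ, net.sps_conv[i].W, st.conv, n_s,
                       net.sps_conv[i].dW, i > 0);
  }
}

// ------------------------------------------------------------- glue ----
static NetCfg read_cfg(List cfg, bool training, bool relaxed) {
  NetCfg c;
  c.T = as<int>(cfg["T"]);
  c.d = as<int>(cfg["d"]);
  c.L = as<int>(cfg["L"]);
  c.pg = as<int>(cfg["patch_grid"]);
  c.mlp_ratio = as<int>(cfg["mlp_ratio"]);
  c.n_classes = as<int>(cfg["n_classes"]);
  c.heads = as<int>(cfg["heads"]);
  c.in_ch = as<int>(cfg["in_channels"]);
  c.map_hw = as<int>(cfg["map_hw"]);
  c.scale_s = as<double>(cfg["scale_s"]);
  c.bn_momentum = as<double>(cfg["bn_momentum"]);
  c.bn_eps = as<double>(cfg["bn_eps"]);
  c.wavelet_enabled = as<bool>(cfg["wavelet_enabled"]);
  c.include_hh = as<bool>(cfg["include_hh"]);
  c.lif.tau = as<double>(cfg["tau"]);
  c.lif.v_th = as<double>(cfg["v_th"]);
  c.lif.v_reset = as<double>(cfg["v_reset"]);
  c.lif.alpha = as<double>(cfg["surrogate_alpha"]);
  c.training = training;
  c.relaxed = relaxed;
  return c;
}

static void put_bn_state(List& st, const std::string& nm, const BNParam& b) {
  st[nm + "_m"] = NumericVector(b.run_m.begin(), b.run_m.end());
  st[nm + "_v"] = NumericVector(b.run_v.begin(), b.run_v.end());
}

static List collect_state(const Net& net, const NetCfg& cfg, List state) {
  List st = clone(state);
  const int S = n_sps_stages(cfg);
  for (int i = 0; i < S; ++i) {
    put_bn_state(st, "sps_bn" + std::to_string(i + 1), net.sps_bn[i]);
  }
  for (int l = 0; l < cfg.L; ++l) {
    std::string t = "blk" + std::to_string(l + 1) + "_";
    const Block& b = net.blocks[l];
    put_bn_state(st, t + "bnq", b.bnq);
    put_bn_state(st, t + "bnk", b.bnk);
    put_bn_state(st, t + "bnv", b.bnv);
    put_bn_state(st, t + "bno", b.bno);
    if (cfg.wavelet_enabled) {
      put_bn_state(st, t + "bnw", b.bnw);
      put_bn_state(st, t + "bnf", b.bnf);
    }
    put_bn_state(st, t + "bn1", b.bn1);
    put_bn_state(st, t + "bn2", b.bn2);
  }
  return st;
}

static void add_grad(List& g, const std::string& nm, const mat& dW) {
  g[nm] = NumericMatrix(dW.n_rows, dW.n_cols, dW.begin());
}

static void add_bn_grad(List& g, const std::string& nm, const BNParam& b) {
  g[nm + "_g"] = NumericVector(b.dgamma.begin(), b.dgamma.end());
  g[nm + "_b"] = NumericVector(b.dbeta.begin(), b.dbeta.end());
}

// [[Rcpp::export]]
List cpp_forward(List params, List state, List cfg_list, NumericMatrix x,
                 int B, bool training, bool record, bool relaxed) {
  NetCfg cfg = read_cfg(cfg_list, training, relaxed);
  Net net = load_net(params, state, cfg);
  mat X0(x.begin(), x.nrow(), x.ncol());
  FwdCtx ctx;
  SpikeProbe probe;
  probe.active = record;
  mat logits = forward_pass(net, cfg, X0, B, ctx, probe);
  List out;
  out["logits"] = NumericMatrix(logits.n_rows, logits.n_cols, logits.begin());
  if (training) out["state"] = collect_state(net, cfg, state);
  if (record) {
    out["layer_names"] = wrap(probe.names);
    out["layer_rates"] = wrap(probe.rates);
    out["layer_counts"] = wrap(probe.counts);
    LogicalVector bin(probe.binary.size());
    for (size_t i = 0; i < probe.binary.size(); ++i) bin[i] = probe.binary[i];
    out["layer_binary"] = bin;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_fwd_bwd(List params, List state, List cfg_list, NumericMatrix x,
                 int B, IntegerVector labels, double lambda_l1, bool relaxed) {
  NetCfg cfg = read_cfg(cfg_list, true, relaxed);
  Net net = load_net(params, state, cfg);
  mat X0(x.begin(), x.nrow(), x.ncol());
  FwdCtx ctx;
  SpikeProbe probe;
  probe.active = true;  // cheap; supplies the per-epoch spiking-rate metric
  probe.check_binary = false;
  mat logits = forward_pass(net, cfg, X0, B, ctx, probe);

  // softmax cross-entropy, mean over the batch
  mat P = logits;
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    const double m = P.row(b).max();
    rowvec e = arma::exp(P.row(b) - m);
    const double Z = arma::accu(e);
    P.row(b) = e / Z;
    loss -= std::log(std::max(P(b, labels[b]), 1e-300));
  }
  loss /= B;
  mat dlogits = P;
  for (int b = 0; b < B; ++b) dlogits(b, labels[b]) -= 1.0;
  dlogits /= (double)B;

  backward_pass(net, cfg, dlogits, ctx);

  // optional L1 sparsity on the learned wavelet filters
  if (cfg.wavelet_enabled && lambda_l1 > 0) {
    for (int l = 0; l < cfg.L; ++l) {
      mat& W = net.blocks[l].wav.W;
      loss += lambda_l1 * arma::accu(arma::abs(W));
      net.blocks[l].wav.dW += lambda_l1 * arma::sign(W);
    }
  }

  List g;
  const int S = n_sps_stages(cfg);
  for (int i = 0; i < S; ++i) {
    std::string t = std::to_string(i + 1);
    add_grad(g, "sps_conv" + t, net.sps_conv[i].dW);
    add_bn_grad(g, "sps_bn" + t, net.sps_bn[i]);
  }
  for (int l = 0; l < cfg.L; ++l) {
    std::string t = "blk" + std::to_string(l + 1) + "_";
    Block& b = net.blocks[l];
    add_grad(g, t + "wq", b.wq.dW);
    add_grad(g, t + "wk", b.wk.dW);
    add_grad(g, t + "wv", b.wv.dW);
    add_grad(g, t + "wo", b.wo.dW);
    add_bn_grad(g, t + "bnq", b.bnq);
    add_bn_grad(g, t + "bnk", b.bnk);
    add_bn_grad(g, t + "bnv", b.bnv);
    add_bn_grad(g, t + "bno", b.bno);
    if (cfg.wavelet_enabled) {
      add_grad(g, t + "wav", b.wav.dW);
      add_bn_grad(g, t + "bnw", b.bnw);
      add_grad(g, t + "wf", b.wf.dW);
      add_bn_grad(g, t + "bnf", b.bnf);
    }
    add_grad(g, t + "w1", b.w1.dW);
    add_grad(g, t + "w2", b.w2.dW);
    add_bn_grad(g, t + "bn1", b.bn1);
    add_bn_grad(g, t + "bn2", b.bn2);
  }
  add_grad(g, "head_W", net.head.dW);
  g["head_b"] = NumericVector(net.dhead_b.begin(), net.dhead_b.end());

  double tot = 0, cnt = 0;
  for (size_t i = 0; i < probe.rates.size(); ++i) {
    tot += probe.rates[i] * probe.counts[i];
    cnt += probe.counts[i];
  }

  List out;
  out["loss"] = loss;
  out["logits"] = NumericMatrix(logits.n_rows, logits.n_cols, logits.begin());
  out["grads"] = g;
  out["state"] = collect_state(net, cfg, state);
  out["spike_rate"] = cnt > 0 ? tot / cnt : 0.0;
  return out;
}
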