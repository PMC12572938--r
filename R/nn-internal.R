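# Internal reference implementation of the network layers.
#
# Feature tensors are matrices with rows ordered (time step, batch item,
# pixel) -- time-major, pixels in column-major image order -- and one column
# per feature channel, the same layout the compiled engine uses. These R
# versions are the readable reference: tests check the compiled forward pass
# against them, and the exported per-operation functions (form_qkv,
# spiking_attention, wavelet_branch, sps, ...) wrap them.

r_bn_fwd <- function(X, gamma, beta, run_m, run_v, training, momentum = 0.1,
                     eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    va <- colMeans(sweep(X, 2, mu)^2)
    xhat <- sweep(sweep(X, 2, mu), 2, sqrt(va + eps), "/")
    run_m <- (1 - momentum) * run_m + momentum * mu
    run_v <- (1 - momentum) * run_v + momentum * va
  } else {
    xhat <- sweep(sweep(X, 2, run_m), 2, sqrt(run_v + eps), "/")
  }
  list(out = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       run_m = run_m, run_v = run_v)
}

r_lif_fwd <- function(X, T_steps, lif, relaxed = FALSE) {
  RB <- nrow(X) / T_steps
  S <- matrix(0, nrow(X), ncol(X))
  V <- matrix(0, RB, ncol(X))
  for (t in seq_len(T_steps)) {
    rows <- ((t - 1) * RB + 1):(t * RB)
    H <- V + (X[rows, , drop = FALSE] - (V - lif$v_reset)) / lif$tau
    St <- if (relaxed) 1 / (1 + exp(-lif$surrogate_alpha * (H - lif$v_th)))
          else (H >= lif$v_th) + 0
    V <- H * (1 - St) + lif$v_reset * St
    S[rows, ] <- St
  }
  S
}

# 3x3 same-padded convolution; W is an array dim c(3, 3, cin, cout)
r_conv_fwd <- function(X, W, H, Wd, n_samp) {
  cin <- dim(W)[3]; cout <- dim(W)[4]
  P <- H * Wd
  Xa <- rbind(X, 0)
  zrow <- nrow(Xa)
  px <- rep(0:(Wd - 1), each = H)
  py <- rep(0:(H - 1), times = Wd)
  base <- rep((0:(n_samp - 1)) * P, each = P)
  patches <- matrix(0, nrow(X), 9 * cin)
  for (kx in 0:2) for (ky in 0:2) {
    sy <- py + ky - 1; sx <- px + kx - 1
    q <- sx * H + sy + 1
    q[sy < 0 | sy >= H | sx < 0 | sx >= Wd] <- NA
    gidx <- base + rep(q, times = n_samp)
    gidx[is.na(gidx)] <- zrow
    cols <- ky + 3 * kx + 1 + 9 * (seq_len(cin) - 1)
    patches[, cols] <- Xa[gidx, , drop = FALSE]
  }
  patches %*% matrix(W, 9 * cin, cout)
}

# 2x2 max pooling with stride 2 on the pixel axis
r_pool_fwd <- function(X, H, Wd, n_samp) {
  Ho <- H / 2; Wo <- Wd / 2
  P <- H * Wd; Po <- Ho * Wo
  xo <- rep(0:(Wo - 1), each = Ho)
  yo <- rep(0:(Ho - 1), times = Wo)
  base_i <- rep((0:(n_samp - 1)) * P, each = Po)
  gather <- function(dy, dx) {
    X[base_i + rep((2 * xo + dx) * H + 2 * yo + dy + 1, times = n_samp), ,
      drop = FALSE]
  }
  pmax(gather(0, 0), gather(1, 0), gather(0, 1), gather(1, 1))
}

# token-grid Haar: corner row indices within one g x g sample
r_haar_corners <- function(g) {
  go <- g / 2
  xo <- rep(0:(go - 1), each = go)
  yo <- rep(0:(go - 1), times = go)
  list(a = (2 * xo) * g + 2 * yo + 1,        # (row y,   col x)
       b = (2 * xo + 1) * g + 2 * yo + 1,    # (row y,   col x+1)
       cc = (2 * xo) * g + 2 * yo + 2,       # (row y+1, col x)
       d = (2 * xo + 1) * g + 2 * yo + 2,    # (row y+1, col x+1)
       q = go * go)
}

r_haar_analyze <- function(X, g, n_samp, include_hh) {
  co <- r_haar_corners(g)
  P <- g * g
  base_in <- rep((0:(n_samp - 1)) * P, each = co$q)
  ga <- function(idx) X[base_in + rep(idx, times = n_samp), , drop = FALSE]
  a <- ga(co$a); b <- ga(co$b); cc <- ga(co$cc); d <- ga(co$d)
  out <- cbind((a + b + cc + d) / 2, (a - b + cc - d) / 2,
               (a + b - cc - d) / 2)
  if (include_hh) out <- cbind(out, (a - b - cc + d) / 2)
  out
}

r_haar_synthesize <- function(S, g, n_samp, d) {
  co <- r_haar_corners(g)
  P <- g * g
  ll <- S[, seq_len(d), drop = FALSE]
  lh <- S[, d + seq_len(d), drop = FALSE]
  hl <- S[, 2 * d + seq_len(d), drop = FALSE]
  hh <- S[, 3 * d + seq_len(d), drop = FALSE]
  X <- matrix(0, n_samp * P, d)
  base_in <- rep((0:(n_samp - 1)) * P, each = co$q)
  sc <- function(idx, val) { X[base_in + rep(idx, times = n_samp), ] <<- val; NULL }
  sc(co$a, (ll + lh + hl + hh) / 2)
  sc(co$b, (ll - lh + hl - hh) / 2)
  sc(co$cc, (ll + lh - hl - hh) / 2)
  sc(co$d, (ll - lh - hl + hh) / 2)
  X
}

# spiking attention core: per (t, b) sample and head, s * (Q K^T) V
r_attn_core <- function(Q, K, V, n_samp, N, d, heads, scale_s) {
  dh <- d / heads
  A <- matrix(0, nrow(Q), d)
  for (s in seq_len(n_samp)) {
    rows <- ((s - 1) * N + 1):(s * N)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      Vh <- V[rows, cols, drop = FALSE]
      A[rows, cols] <- scale_s * (Qh %*% t(Kh)) %*% Vh
    }
  }
  A
}

# linear + BN + LIF unit (the recurring Eq-15/17 pattern)
r_lin_bn_lif <- function(X, W, bn, T_steps, lif, training, relaxed = FALSE) {
  z <- r_bn_fwd(X %*% W, bn$g, bn$b, bn$m, bn$v, training)
  r_lif_fwd(z$out, T_steps, lif, relaxed)
}

sub_bn <- function(params, state, nm) {
  list(g = params[[paste0(nm, "_g")]], b = params[[paste0(nm, "_b")]],
       m = state[[paste0(nm, "_m")]], v = state[[paste0(nm, "_v")]])
}

# ------------------------------------------------------------------------
# Reference forward pass over a full batch. Returns logits and, when
# `record = TRUE`, every LIF layer's spike matrix for instrumentation.
r_forward <- function(params, state, cfg, X0, B, training = FALSE,
                      record = FALSE) {
  T_steps <- cfg$T
  lif <- cfg$lif
  rec <- list()
  keep <- function(nm, S) if (record) rec[[nm]] <<- S
  S_n <- n_stages(cfg)
  X <- X0
  H <- cfg$map_hw; Wd <- cfg$map_hw
  n_samp <- T_steps * B
  for (i in seq_len(S_n)) {
    Z <- r_conv_fwd(X, params[[paste0("sps_conv", i)]], H, Wd, n_samp)
    bn <- sub_bn(params, state, paste0("sps_bn", i))
    Z <- r_bn_fwd(Z, bn$g, bn$b, bn$m, bn$v, training)$out
    Sp <- r_lif_fwd(Z, T_steps, lif)
    keep(paste0("sps_lif", i), Sp)
    X <- r_pool_fwd(Sp, H, Wd, n_samp)
    H <- H / 2; Wd <- Wd / 2
  }
  N <- H * Wd
  for (l in seq_len(cfg$L)) {
    p <- function(nm) params[[paste0("blk", l, "_", nm)]]
    bnm <- function(nm) sub_bn(params, state, paste0("blk", l, "_", nm))
    Q <- r_lin_bn_lif(X, p("wq"), bnm("bnq"), T_steps, lif, training)
    K <- r_lin_bn_lif(X, p("wk"), bnm("bnk"), T_steps, lif, training)
    V <- r_lin_bn_lif(X, p("wv"), bnm("bnv"), T_steps, lif, training)
    keep(paste0("blk", l, "_q"), Q); keep(paste0("blk", l, "_k"), K)
    keep(paste0("blk", l, "_v"), V)
    A <- r_attn_core(Q, K, V, n_samp, N, cfg$d, cfg$heads, cfg$scale_s)
    Xattn <- r_lif_fwd(A, T_steps, lif)
    keep(paste0("blk", l, "_attn"), Xattn)
    Xo <- r_lin_bn_lif(Xattn, p("wo"), bnm("bno"), T_steps, lif, training)
    keep(paste0("blk", l, "_proj"), Xo)
    if (cfg$wavelet_enabled) {
      Sub <- r_haar_analyze(X, cfg$patch_grid, n_samp, cfg$include_hh)
      gq <- cfg$patch_grid / 2
      Zw <- r_conv_fwd(Sub, p("wav"), gq, gq, n_samp)
      bw <- bnm("bnw")
      Zw <- r_bn_fwd(Zw, bw$g, bw$b, bw$m, bw$v, training)$out
      Sw <- r_lif_fwd(Zw, T_steps, lif)
      keep(paste0("blk", l, "_wav"), Sw)
      Xrec <- r_haar_synthesize(Sw, cfg$patch_grid, n_samp, cfg$d)
      Xswsa <- r_lin_bn_lif(cbind(Xo, Xrec), p("wf"), bnm("bnf"), T_steps,
                            lif, training)
      keep(paste0("blk", l, "_fuse"), Xswsa)
    } else {
      Xswsa <- Xo
    }
    X1 <- X + Xswsa
    Hm <- r_lin_bn_lif(X1, p("w1"), bnm("bn1"), T_steps, lif, training)
    keep(paste0("blk", l, "_mlp1"), Hm)
    Xmlp <- r_lin_bn_lif(Hm, p("w2"), bnm("bn2"), T_steps, lif, training)
    keep(paste0("blk", l, "_mlp2"), Xmlp)
    X <- X1 + Xmlp
  }
  G <- matrix(0, n_samp, cfg$d)
  for (s in seq_len(n_samp)) {
    G[s, ] <- colMeans(X[((s - 1) * N + 1):(s * N), , drop = FALSE])
  }
  Fm <- matrix(0, B, cfg$d)
  for (t in seq_len(T_steps)) Fm <- Fm + G[((t - 1) * B + 1):(t * B), ,
                                           drop = FALSE]
  Fm <- Fm / T_steps
  logits <- sweep(Fm %*% params$head_W, 2, params$head_b, "+")
  list(logits = logits, spikes = rec, tokens = X)
}

n_stages <- function(cfg) as.integer(round(log2(cfg$map_hw / cfg$patch_grid)))

# ------------------------------------------------------------------------
# Parameter initialization (He-scaled Gaussians; wavelet filter starts as
# an LL identity passthrough so an untrained branch transmits the
# approximation band and nothing else).

init_conv_w <- function(cin, cout) {
  array(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
        dim = c(3, 3, cin, cout))
}

init_lin_w <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

init_wav_w <- function(d, include_hh) {
  cin <- if (include_hh) 4L * d else 3L * d
  W <- array(0, dim = c(3, 3, cin, 4L * d))
  for (ch in seq_len(d)) W[2, 2, ch, ch] <- 1
  W
}

init_bn <- function(params, state, nm, C) {
  params[[paste0(nm, "_g")]] <- rep(1, C)
  params[[paste0(nm, "_b")]] <- rep(0, C)
  state[[paste0(nm, "_m")]] <- rep(0, C)
  state[[paste0(nm, "_v")]] <- rep(1, C)
  list(params = params, state = state)
}

init_net_params <- function(cfg, seed) {
  set.seed(seed)
  params <- list(); state <- list()
  S_n <- n_stages(cfg)
  cin <- cfg$in_channels
  for (i in seq_len(S_n)) {
    cout <- cfg$d %/% 2^(S_n - i)
    if (cout < 1) stop("d too small for ", S_n, " patch-splitting stages")
    params[[paste0("sps_conv", i)]] <- init_conv_w(cin, cout)
    r <- init_bn(params, state, paste0("sps_bn", i), cout)
    params <- r$params; state <- r$state
    cin <- cout
  }
  d <- cfg$d
  for (l in seq_len(cfg$L)) {
    t <- function(nm) paste0("blk", l, "_", nm)
    for (nm in c("wq", "wk", "wv", "wo")) params[[t(nm)]] <- init_lin_w(d, d)
    for (nm in c("bnq", "bnk", "bnv", "bno")) {
      r <- init_bn(params, state, t(nm), d); params <- r$params; state <- r$state
    }
    if (cfg$wavelet_enabled) {
      params[[t("wav")]] <- init_wav_w(d, cfg$include_hh)
      r <- init_bn(params, state, t("bnw"), 4L * d)
      params <- r$params; state <- r$state
      params[[t("wf")]] <- init_lin_w(2L * d, d)
      r <- init_bn(params, state, t("bnf"), d)
      params <- r$params; state <- r$state
    }
    hid <- cfg$mlp_ratio * d
    params[[t("w1")]] <- init_lin_w(d, hid)
    params[[t("w2")]] <- init_lin_w(hid, d)
    r <- init_bn(params, state, t("bn1"), hid); params <- r$params; state <- r$state
    r <- init_bn(params, state, t("bn2"), d); params <- r$params; state <- r$state
  }
  params$head_W <- init_lin_w(d, cfg$n_classes) / sqrt(2)
  params$head_b <- rep(0, cfg$n_classes)
  list(params = params, state = state)
}

# batch array (B, T, C, H, W) -> engine matrix (T*B*P rows, C columns)
batch_to_mat <- function(xb) {
  d <- dim(xb)
  B <- d[1]; T_steps <- d[2]; C <- d[3]; H <- d[4]; W <- d[5]
  out <- matrix(0, T_steps * B * H * W, C)
  for (ch in seq_len(C)) {
    xc <- xb[, , ch, , , drop = FALSE]
    dim(xc) <- c(B, T_steps, H, W)
    out[, ch] <- as.vector(aperm(xc, c(3, 4, 1, 2)))
  }
  out
}

# single window (T, C, H, W) -> engine matrix (B = 1)
window_to_mat <- function(x) {
  batch_to_mat(array(x, dim = c(1, dim(x))))
}
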