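#' Parameters of one spiking wavelet self-attention block
#'
#' Standalone constructor for the per-block parameter set used by
#' [form_qkv()], [attn_project()] and [swsa_block()]: d x d query / key /
#' value / output projections, the wavelet sub-band filter, the 2d -> d
#' fusion projection, and their batch-norm parameters. Inside a
#' [spikewav_model()] the same entries exist with a `blk<l>_` prefix.
#'
#' @param d Embedding dimension.
#' @param heads Attention heads (d divisible by heads).
#' @param scale_s Attention scaling factor.
#' @param patch_grid Token grid side (N = patch_grid^2 tokens).
#' @param include_hh Whether HH joins the wavelet filter input.
#' @param wavelet_enabled Whether the wavelet branch is active.
#' @param seed RNG seed for weight initialization.
#' @return Named parameter list (class `swsa_params`).
#' @export
swsa_params <- function(d = 32, heads = 8, scale_s = 0.125, patch_grid = 4,
                        include_hh = FALSE, wavelet_enabled = TRUE,
                        seed = 1L) {
  if (d %% heads != 0) stop("d must be divisible by heads")
  set.seed(seed)
  p <- list(d = d, heads = heads, scale_s = scale_s,
            patch_grid = patch_grid, include_hh = include_hh,
            wavelet_enabled = wavelet_enabled)
  for (nm in c("wq", "wk", "wv", "wo")) p[[nm]] <- init_lin_w(d, d)
  for (nm in c("bnq", "bnk", "bnv", "bno")) {
    p[[paste0(nm, "_g")]] <- rep(1, d); p[[paste0(nm, "_b")]] <- rep(0, d)
    p[[paste0(nm, "_m")]] <- rep(0, d); p[[paste0(nm, "_v")]] <- rep(1, d)
  }
  if (wavelet_enabled) {
    p$wav <- init_wav_w(d, include_hh)
    p$bnw_g <- rep(1, 4 * d); p$bnw_b <- rep(0, 4 * d)
    p$bnw_m <- rep(0, 4 * d); p$bnw_v <- rep(1, 4 * d)
    p$wf <- init_lin_w(2 * d, d)
    p$bnf_g <- rep(1, d); p$bnf_b <- rep(0, d)
    p$bnf_m <- rep(0, d); p$bnf_v <- rep(1, d)
  }
  class(p) <- "swsa_params"
  p
}

#' Form spiking query, key and value matrices
#'
#' Per time step, `Q = LIF(BN(X W_q))` (and likewise K, V) with the LIF
#' membrane state carried across the T time steps. Outputs are binary.
#'
#' @param x_spikes T x N x d spike token array.
#' @param p A [swsa_params()] list.
#' @param lif A [lif_config()].
#' @return List of binary arrays `Q`, `K`, `V`, each T x N x d.
#' @export
form_qkv <- function(x_spikes, p, lif = lif_config()) {
  if (dim(x_spikes)[3] != p$d) {
    stop("token dimension ", dim(x_spikes)[3], " does not match d = ", p$d)
  }
  X <- tokens_to_mat(x_spikes)
  T_steps <- dim(x_spikes)[1]; N <- dim(x_spikes)[2]
  one <- function(w, bn) {
    S <- r_lin_bn_lif(X, p[[w]], sub_bn(p, p, bn), T_steps, lif, FALSE)
    mat_to_tokens(S, T_steps, 1, N)[[1]]
  }
  list(Q = one("wq", "bnq"), K = one("wk", "bnk"), V = one("wv", "bnv"))
}

#' Spiking self-attention core
#'
#' Computes `LIF(s * (Q K^T) V)` per time step (LIF state carried across
#' time). There is no softmax: with binary Q, K, V the pre-scaling entries
#' of `Q K^T V` are non-negative integers, and the scaling factor `s` only
#' controls their magnitude.
#'
#' @param Q,K,V Binary T x N x d arrays (from [form_qkv()]).
#' @param scale_s Scaling factor.
#' @param heads Attention heads.
#' @param lif A [lif_config()].
#' @return Binary T x N x d spike array.
#' @export
spiking_attention <- function(Q, K, V, scale_s = 0.125, heads = 1,
                              lif = lif_config()) {
  d <- dim(Q)[3]; N <- dim(Q)[2]; T_steps <- dim(Q)[1]
  A <- r_attn_core(tokens_to_mat(Q), tokens_to_mat(K), tokens_to_mat(V),
                   T_steps, N, d, heads, scale_s)
  S <- r_lif_fwd(A, T_steps, lif)
  mat_to_tokens(S, T_steps, 1, N)[[1]]
}

#' Post-attention projection
#'
#' `X' = LIF(BN(Linear(X)))` on the attention output; shape preserved,
#' output binary.
#'
#' @param x Binary T x N x d array.
#' @param p A [swsa_params()] list (uses `wo`, `bno_*`).
#' @param lif A [lif_config()].
#' @return Binary T x N x d array.
#' @export
attn_project <- function(x, p, lif = lif_config()) {
  X <- tokens_to_mat(x)
  T_steps <- dim(x)[1]; N <- dim(x)[2]
  S <- r_lin_bn_lif(X, p$wo, sub_bn(p, p, "bno"), T_steps, lif, FALSE)
  mat_to_tokens(S, T_steps, 1, N)[[1]]
}

#' One spiking wavelet self-attention block
#'
#' The fused operator: the attention path runs [form_qkv()],
#' [spiking_attention()] and [attn_project()]; the wavelet path reshapes
#' the N tokens to their sqrt(N) x sqrt(N) spatial layout per time step,
#' Haar-analyzes them, filters the sub-bands with a learned spiking
#' convolution and Haar-synthesizes a reconstruction. The two results are
#' concatenated channel-wise (2d), projected back to d, normalized and
#' passed through a LIF layer, so the output is binary and shape-compatible
#' with the residual stream. With `wavelet_enabled = FALSE` the block
#' reduces exactly to plain spiking self-attention (the Eq.-15-to-17
#' pipeline alone).
#'
#' @param x T x N x d spike token array; N must equal `patch_grid^2`.
#' @param p A [swsa_params()] list.
#' @param lif A [lif_config()].
#' @return Binary T x N x d array (pre-residual SWSA output).
#' @export
swsa_block <- function(x, p, lif = lif_config()) {
  T_steps <- dim(x)[1]; N <- dim(x)[2]; d <- dim(x)[3]
  g <- as.integer(round(sqrt(N)))
  if (g * g != N) stop("token count N = ", N, " must be a perfect square")
  qkv <- form_qkv(x, p, lif)
  xa <- spiking_attention(qkv$Q, qkv$K, qkv$V, p$scale_s, p$heads, lif)
  xo <- attn_project(xa, p, lif)
  if (!isTRUE(p$wavelet_enabled)) return(xo)
  X <- tokens_to_mat(x)
  Sub <- r_haar_analyze(X, g, T_steps, p$include_hh)
  Zw <- r_conv_fwd(Sub, p$wav, g / 2, g / 2, T_steps)
  Zw <- r_bn_fwd(Zw, p$bnw_g, p$bnw_b, p$bnw_m, p$bnw_v, FALSE)$out
  Sw <- r_lif_fwd(Zw, T_steps, lif)
  Xrec <- r_haar_synthesize(Sw, g, T_steps, d)
  Xcomb <- cbind(tokens_to_mat(xo), Xrec)
  S <- r_lin_bn_lif(Xcomb, p$wf, sub_bn(p, p, "bnf"), T_steps, lif, FALSE)
  mat_to_tokens(S, T_steps, 1, N)[[1]]
}
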