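#' Model architecture configuration
#'
#' Hyperparameters of the spiking wavelet transformer: `T` simulation time
#' steps of the SNN, a convolutional spiking patch-splitting front end that
#' reduces the `map_hw` x `map_hw` topographic input to a
#' `patch_grid` x `patch_grid` token grid with `d` embedding channels, `L`
#' encoder blocks (spiking wavelet self-attention + spiking MLP, both with
#' residual streams), global average pooling and a linear classification
#' head (no spiking layer on the head, so real-valued scores feed the
#' cross-entropy loss).
#'
#' @param T_steps SNN simulation time steps (paper setting: 4).
#' @param L Number of encoder blocks.
#' @param d Embedding dimension (divisible by `heads`).
#' @param patch_grid Tokens per side; `patch_grid^2` tokens. Must be even
#'   (the wavelet branch halves the token grid) and `map_hw / patch_grid` a
#'   power of two.
#' @param mlp_ratio Hidden expansion of the MLP block.
#' @param n_classes Output classes.
#' @param heads Attention heads.
#' @param scale_s Attention scaling factor applied to `Q K^T V`.
#' @param map_hw Input topographic map side length (power of two).
#' @param in_channels Input feature channels.
#' @param wavelet_enabled If `FALSE` the encoder reduces to plain spiking
#'   self-attention (ablation).
#' @param include_hh If `TRUE` the HH sub-band joins the wavelet filter's
#'   input concatenation; by default only (LL, LH, HL) are filtered.
#' @param lif A [lif_config()].
#' @param bn_momentum,bn_eps Batch-normalization running-stat momentum and
#'   variance floor.
#' @return An object of class `model_config`.
#' @export
model_config <- function(T_steps = 4, L = 2, d = 32, patch_grid = 4,
                         mlp_ratio = 4, n_classes = 2, heads = 8,
                         scale_s = 0.125, map_hw = 32, in_channels = 1,
                         wavelet_enabled = TRUE, include_hh = FALSE,
                         lif = lif_config(), bn_momentum = 0.1,
                         bn_eps = 1e-5) {
  cfg <- list(T = as.integer(T_steps), L = as.integer(L), d = as.integer(d),
              patch_grid = as.integer(patch_grid),
              mlp_ratio = as.integer(mlp_ratio),
              n_classes = as.integer(n_classes), heads = as.integer(heads),
              scale_s = scale_s, map_hw = as.integer(map_hw),
              in_channels = as.integer(in_channels),
              wavelet_enabled = isTRUE(wavelet_enabled),
              include_hh = isTRUE(include_hh), lif = lif,
              bn_momentum = bn_momentum, bn_eps = bn_eps)
  class(cfg) <- "model_config"
  if (cfg$T < 1 || cfg$L < 1) stop("T and L must be >= 1")
  if (cfg$d %% cfg$heads != 0) stop("d must be divisible by heads")
  if (cfg$patch_grid %% 2 != 0) stop("patch_grid must be even (wavelet halving)")
  ratio <- cfg$map_hw / cfg$patch_grid
  if (ratio < 1 || abs(log2(ratio) - round(log2(ratio))) > 1e-9) {
    stop("map_hw / patch_grid must be a power of two")
  }
  cfg
}

# flat config list for the compiled engine
cfg_for_cpp <- function(cfg) {
  list(T = cfg$T, d = cfg$d, L = cfg$L, patch_grid = cfg$patch_grid,
       mlp_ratio = cfg$mlp_ratio, n_classes = cfg$n_classes,
       heads = cfg$heads, in_channels = cfg$in_channels,
       map_hw = cfg$map_hw, scale_s = cfg$scale_s,
       bn_momentum = cfg$bn_momentum, bn_eps = cfg$bn_eps,
       wavelet_enabled = cfg$wavelet_enabled, include_hh = cfg$include_hh,
       tau = cfg$lif$tau, v_th = cfg$lif$v_th, v_reset = cfg$lif$v_reset,
       surrogate_alpha = cfg$lif$surrogate_alpha)
}

#' Construct a spiking wavelet transformer model
#'
#' Initializes all parameters (He-scaled Gaussian weights; the wavelet
#' sub-band filter starts as an LL identity passthrough) from a seeded RNG
#' and zeroed batch-norm running statistics.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `spikewav_model` with elements `cfg`,
#'   `params` (named list of weight arrays), `state` (batch-norm running
#'   moments) and `seed`.
#' @export
spikewav_model <- function(cfg = model_config(), seed = 1L) {
  init <- init_net_params(cfg, seed)
  structure(list(cfg = cfg, params = init$params, state = init$state,
                 seed = as.integer(seed)), class = "spikewav_model")
}

#' Number of trainable parameters
#'
#' @param model A `spikewav_model`.
#' @return Integer parameter count (deterministic from the configuration).
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.spikewav_model <- function(x, ...) {
  cfg <- x$cfg
  cat("<spikewav_model> T=", cfg$T, " L=", cfg$L, " d=", cfg$d,
      " tokens=", cfg$patch_grid^2, " heads=", cfg$heads,
      " wavelet=", cfg$wavelet_enabled, "\n  parameters: ", n_params(x),
      "\n", sep = "")
  invisible(x)
}

#' Forward pass of the model
#'
#' Runs a batch of encoded windows through the network: spiking patch
#' splitting, `L` encoder blocks (spiking wavelet self-attention and spiking
#' MLP, each with a residual add), global average pooling over tokens, mean
#' over time steps, and the linear head. All LIF membrane states start at 0
#' for every call, so repeated calls on the same batch are identical.
#'
#' @param model A `spikewav_model`.
#' @param x Either an `encoded_dataset`, a (B, T, C, H, W) array, or a
#'   single (T, C, H, W) window array.
#' @param training If `TRUE`, batch statistics are used for normalization
#'   and running moments are updated (returned in the `state` attribute).
#' @param record If `TRUE`, attach per-LIF-layer spiking rates and binarity
#'   flags as attribute `"spikes"`.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation).
#' @return B x n_classes matrix of class scores.
#' @export
model_forward <- function(model, x, training = FALSE, record = FALSE,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  xb <- as_batch_array(x, model$cfg)
  B <- dim(xb)[1]
  X0 <- batch_to_mat(xb)
  if (engine == "cpp") {
    out <- cpp_forward(model$params, model$state, cfg_for_cpp(model$cfg), X0,
                       B, training, record, FALSE)
    logits <- out$logits
    if (record) {
      attr(logits, "spikes") <- list(names = out$layer_names,
                                     rates = out$layer_rates,
                                     counts = out$layer_counts,
                                     binary = out$layer_binary)
    }
    if (training) attr(logits, "state") <- out$state
  } else {
    out <- r_forward(model$params, model$state, model$cfg, X0, B, training,
                     record)
    logits <- out$logits
    if (record) attr(logits, "spikes") <- out$spikes
  }
  logits
}

as_batch_array <- function(x, cfg) {
  if (inherits(x, "encoded_dataset")) return(x$x)
  if (inherits(x, "encoded_window")) x <- x$x
  d <- dim(x)
  if (length(d) == 4) x <- array(x, dim = c(1, d))
  if (length(dim(x)) != 5) stop("expected a (B, T, C, H, W) input array")
  d <- dim(x)
  if (d[2] != cfg$T || d[3] != cfg$in_channels || d[4] != cfg$map_hw ||
      d[5] != cfg$map_hw) {
    stop("input shape (", paste(d[-1], collapse = "x"),
         ") does not match model config (", cfg$T, "x", cfg$in_channels,
         "x", cfg$map_hw, "x", cfg$map_hw, ")")
  }
  x
}

#' Predict class labels
#'
#' Argmax of the class scores with a deterministic tie-break toward the
#' lower class index. Labels are 0-based.
#'
#' @param object A `spikewav_model`.
#' @param x Input accepted by [model_forward()].
#' @param ... Unused.
#' @return Integer vector of predicted labels (0-based), one per batch row.
#' @export
predict.spikewav_model <- function(object, x, ...) {
  scores <- model_forward(object, x)
  apply(scores, 1, which.max) - 1L
}

#' Spiking patch splitting (SPS)
#'
#' The convolutional spike-emitting front end: repeated
#' (3x3 conv, batch norm, LIF, 2x2 max-pool) stages that downsample the
#' `map_hw` grid to `patch_grid` and widen channels to `d`. Output values
#' are binary spikes.
#'
#' @param model A `spikewav_model`.
#' @param x A single (T, C, H, W) encoded window or (B, T, C, H, W) batch.
#' @return T x N x d array of spike tokens for a single window, or a
#'   B-list of such arrays for a batch.
#' @export
sps <- function(model, x) {
  cfg <- model$cfg
  xb <- as_batch_array(x, cfg)
  B <- dim(xb)[1]
  X0 <- batch_to_mat(xb)
  X <- X0
  H <- cfg$map_hw; Wd <- cfg$map_hw
  n_samp <- cfg$T * B
  for (i in seq_len(n_stages(cfg))) {
    Z <- r_conv_fwd(X, model$params[[paste0("sps_conv", i)]], H, Wd, n_samp)
    bn <- sub_bn(model$params, model$state, paste0("sps_bn", i))
    Z <- r_bn_fwd(Z, bn$g, bn$b, bn$m, bn$v, FALSE)$out
    X <- r_pool_fwd(r_lif_fwd(Z, cfg$T, cfg$lif), H, Wd, n_samp)
    H <- H / 2; Wd <- Wd / 2
  }
  toks <- mat_to_tokens(X, cfg$T, B, H * Wd)
  if (B == 1) toks[[1]] else toks
}

# engine matrix -> per-batch-item T x N x d arrays
mat_to_tokens <- function(X, T_steps, B, N) {
  d <- ncol(X)
  lapply(seq_len(B), function(b) {
    out <- array(0, dim = c(T_steps, N, d))
    for (t in seq_len(T_steps)) {
      rows <- ((t - 1) * B + (b - 1)) * N + seq_len(N)
      out[t, , ] <- X[rows, , drop = FALSE]
    }
    out
  })
}

tokens_to_mat <- function(x) {
  d <- dim(x)  # T x N x d
  X <- matrix(0, d[1] * d[2], d[3])
  for (t in seq_len(d[1])) {
    X[(t - 1) * d[2] + seq_len(d[2]), ] <- x[t, , ]
  }
  X
}

#' Spiking MLP block
#'
#' Two (linear, batch norm, LIF) stages expanding `d` to `mlp_ratio * d`
#' and back. The caller owns the residual add.
#'
#' @param x T x N x d spike token array.
#' @param params Named list with `w1`, `w2` and BN entries `bn1_*`,
#'   `bn2_*` (as produced inside [spikewav_model()], unprefixed).
#' @param lif A [lif_config()].
#' @return T x N x d binary spike array.
#' @export
mlp_block <- function(x, params, lif = lif_config()) {
  X <- tokens_to_mat(x)
  T_steps <- dim(x)[1]
  st <- list(bn1_m = params$bn1_m, bn1_v = params$bn1_v,
             bn2_m = params$bn2_m, bn2_v = params$bn2_v)
  Hm <- r_lin_bn_lif(X, params$w1, sub_bn(params, st, "bn1"), T_steps, lif,
                     FALSE)
  Y <- r_lin_bn_lif(Hm, params$w2, sub_bn(params, st, "bn2"), T_steps, lif,
                    FALSE)
  mat_to_tokens(Y, T_steps, 1, dim(x)[2])[[1]]
}
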