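#' Single-level orthonormal 2D Haar analysis
#'
#' Decomposes a feature map into four half-resolution sub-bands. On each
#' non-overlapping 2x2 block `[[a, b], [c, d]]` (rows x columns):
#' `ll = (a+b+c+d)/2`, `lh = (a-b+c-d)/2`, `hl = (a+b-c-d)/2`,
#' `hh = (a-b-c+d)/2`. The transform is orthonormal: it preserves the
#' Euclidean norm exactly (Parseval), so the analysis operator is an
#' isometry and the synthesis ([haar_idwt2()]) is its exact inverse.
#'
#' @param x An H x W matrix or a C x H x W array with even H and W.
#' @return An object of class `subbands`: list of `ll`, `lh`, `hl`, `hh`,
#'   each of spatial size H/2 x W/2 (with the leading channel axis kept if
#'   the input had one).
#' @export
haar_dwt2 <- function(x) {
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, dim = c(1, dim(x)))
  d <- dim(x)
  if (length(d) != 3) stop("input must be H x W or C x H x W")
  H <- d[2]; W <- d[3]
  if (H %% 2 != 0 || W %% 2 != 0) stop("spatial dimensions must be even")
  oi <- seq(1, H, by = 2); oj <- seq(1, W, by = 2)
  a <- x[, oi, oj, drop = FALSE]; b <- x[, oi, oj + 1, drop = FALSE]
  cc <- x[, oi + 1, oj, drop = FALSE]; dd <- x[, oi + 1, oj + 1, drop = FALSE]
  sb <- list(ll = (a + b + cc + dd) / 2, lh = (a - b + cc - dd) / 2,
             hl = (a + b - cc - dd) / 2, hh = (a - b - cc + dd) / 2)
  if (was_mat) sb <- lapply(sb, function(z) array(z, dim = dim(z)[2:3]))
  structure(sb, class = "subbands")
}

#' Single-level orthonormal 2D Haar synthesis
#'
#' Exact inverse of [haar_dwt2()]: reconstructs the full-resolution map from
#' the four sub-bands, `a = (ll+lh+hl+hh)/2` and so on, to machine
#' precision.
#'
#' @param sb A `subbands` object (or a plain list with `ll`, `lh`, `hl`,
#'   `hh` of identical shapes).
#' @return The reconstructed H x W matrix or C x H x W array.
#' @export
haar_idwt2 <- function(sb) {
  shp <- lapply(sb[c("ll", "lh", "hl", "hh")], dim2)
  if (length(unique(vapply(shp, paste, character(1), collapse = "x"))) != 1) {
    stop("sub-band shapes must be identical")
  }
  was_mat <- is.matrix(sb$ll)
  band <- function(z) if (was_mat) array(z, dim = c(1, dim(z))) else z
  ll <- band(sb$ll); lh <- band(sb$lh); hl <- band(sb$hl); hh <- band(sb$hh)
  d <- dim(ll)
  H <- 2 * d[2]; W <- 2 * d[3]
  x <- array(0, dim = c(d[1], H, W))
  oi <- seq(1, H, by = 2); oj <- seq(1, W, by = 2)
  x[, oi, oj] <- (ll + lh + hl + hh) / 2
  x[, oi, oj + 1] <- (ll - lh + hl - hh) / 2
  x[, oi + 1, oj] <- (ll + lh - hl - hh) / 2
  x[, oi + 1, oj + 1] <- (ll - lh - hl + hh) / 2
  if (was_mat) array(x, dim = c(H, W)) else x
}

#' Initialize the learned sub-band filter of the wavelet branch
#'
#' The branch concatenates the LL, LH and HL sub-bands (3C channels; HH is
#' excluded by default), applies a 3x3 same-padded convolution to 4C
#' channels, batch-style normalization and a LIF spiking layer, and splits
#' the result back into four spike-valued sub-bands for synthesis. Weights
#' start as an identity passthrough: the LL quarter of the output channels
#' copies the LL input at the center tap and all other weights are zero, so
#' an untrained branch transmits the approximation band and injects no
#' noise.
#'
#' @param C Feature channels per sub-band.
#' @param include_hh If `TRUE`, HH joins the concatenation (4C input
#'   channels).
#' @param seed Unused at identity initialization; kept for future random
#'   initialization schemes.
#' @return Parameter list with conv weights `W` (3 x 3 x Cin x 4C), BN
#'   `gamma`/`beta` and running moments, and the `lif_config`.
#' @export
wavelet_branch_params <- function(C, include_hh = FALSE, seed = NULL) {
  cin <- if (include_hh) 4L * C else 3L * C
  cout <- 4L * C
  W <- array(0, dim = c(3, 3, cin, cout))
  for (ch in seq_len(C)) W[2, 2, ch, ch] <- 1  # LL -> LL passthrough
  list(W = W, gamma = rep(1, cout), beta = rep(0, cout),
       run_mean = rep(0, cout), run_var = rep(1, cout),
       lif = lif_config(), include_hh = include_hh)
}

#' Filter wavelet sub-bands with a learned spiking convolution
#'
#' Implements the learned part of the wavelet branch on one feature map's
#' sub-bands: channel-wise concatenation of (LL, LH, HL) — HH optionally
#' included — a 3x3 convolution producing 4C channels, normalization using
#' the stored running moments, a LIF layer (T = 1, fresh state), and a
#' 4-way split into spike-valued sub-bands.
#'
#' @param sb A `subbands` object with C x h x w bands.
#' @param params A [wavelet_branch_params()] list.
#' @return A `subbands` object of binary spike maps, each C x h x w.
#' @export
subband_filter <- function(sb, params) {
  C <- dim(sb$ll)[1]
  bands <- if (isTRUE(params$include_hh)) list(sb$ll, sb$lh, sb$hl, sb$hh)
           else list(sb$ll, sb$lh, sb$hl)
  xin <- do.call(abind1, bands)                       # Cin x h x w
  conv <- conv3x3_ref(xin, params$W)                  # 4C x h x w
  z <- bn_apply_ref(conv, params$gamma, params$beta,
                    params$run_mean, params$run_var)
  h <- dim(z)[2]; w <- dim(z)[3]
  flat <- matrix(aperm(z, c(2, 3, 1)), nrow = 1)      # single time step
  s <- lif_sequence(array(flat, dim = c(1, length(flat))), params$lif)
  s <- aperm(array(s, dim = c(h, w, dim(z)[1])), c(3, 1, 2))
  structure(list(ll = s[seq_len(C), , , drop = FALSE],
                 lh = s[C + seq_len(C), , , drop = FALSE],
                 hl = s[2 * C + seq_len(C), , , drop = FALSE],
                 hh = s[3 * C + seq_len(C), , , drop = FALSE]),
            class = "subbands")
}

#' Wavelet branch: analyze, filter, synthesize
#'
#' The full frequency-domain path of the spiking wavelet attention block on
#' a single feature map: Haar analysis, learned spiking sub-band filtering,
#' Haar synthesis. Output has the input's spatial shape.
#'
#' @param x_t A C x H x W feature map (H, W even).
#' @param params A [wavelet_branch_params()] list (created to match C if
#'   omitted).
#' @return C x H x W reconstruction.
#' @export
wavelet_branch <- function(x_t, params = NULL) {
  if (is.matrix(x_t)) x_t <- array(x_t, dim = c(1, dim(x_t)))
  if (is.null(params)) params <- wavelet_branch_params(dim(x_t)[1])
  haar_idwt2(subband_filter(haar_dwt2(x_t), params))
}

# concatenate C x h x w arrays along the channel axis
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1], 0)), d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

# 3x3 same-padded convolution on a C x H x W array (reference path)
conv3x3_ref <- function(x, W) {
  d <- dim(x); H <- d[2]; Wd <- d[3]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  stopifnot(d[1] == cin)
  out <- array(0, dim = c(cout, H, Wd))
  xp <- array(0, dim = c(cin, H + 2, Wd + 2))
  xp[, 2:(H + 1), 2:(Wd + 1)] <- x
  for (dy in 0:2) for (dx in 0:2) {
    patch <- xp[, dy + seq_len(H), dx + seq_len(Wd), drop = FALSE]
    pm <- matrix(patch, nrow = cin)                   # cin x (H*W)
    wm <- matrix(W[dy + 1, dx + 1, , ], nrow = cin)   # cin x cout
    out <- out + array(t(wm) %*% pm, dim = c(cout, H, Wd))
  }
  out
}

# normalization with fixed moments, per channel (reference path)
bn_apply_ref <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  C <- dim(x)[1]
  for (ch in seq_len(C)) {
    x[ch, , ] <- gamma[ch] * (x[ch, , ] - mean[ch]) / sqrt(var[ch] + eps) +
      beta[ch]
  }
  x
}
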