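#' Mean power per channel of a decision window
#'
#' Mean squared amplitude of each channel. Intended for windows already
#' band-limited (e.g. alpha via [extract_band()]): the result is the
#' channel's band power.
#'
#' @param win An `eeg_window` (or a channels x samples matrix).
#' @return Numeric vector of per-channel powers.
#' @export
channel_power <- function(win) {
  data <- if (inherits(win, "eeg_window")) win$data else win
  if (is.null(dim(data)) || ncol(data) < 1) stop("empty window")
  rowMeans(data^2)
}

#' Inverse-distance interpolation weights for a topographic grid
#'
#' Precomputes the linear operator mapping per-channel values to an H x W
#' head-plane image: each pixel inside the unit disc is an inverse-distance
#' weighted (power 2) average of its `k` nearest electrodes; pixels outside
#' the disc are zero. Because the weights do not depend on the values, the
#' projection is linear and never overshoots the value range.
#'
#' @param montage A `montage`.
#' @param H,W Grid size in pixels.
#' @param k Number of nearest electrodes per pixel.
#' @return List with `weights` ((H*W) x n_channels matrix, row-major pixel
#'   order by image row) and `inside` (logical mask of in-disc pixels).
#' @export
topomap_weights <- function(montage, H = 32, W = 32, k = 4) {
  validate_montage(montage)
  nch <- nrow(montage$positions)
  k <- min(k, nch)
  gx <- seq(-1, 1, length.out = W)
  gy <- seq(1, -1, length.out = H)          # top row = nasion (y = +1)
  px <- rep(gx, times = H)
  py <- rep(gy, each = W)
  inside <- px^2 + py^2 <= 1
  d2 <- outer(px, montage$positions[, 1], "-")^2 +
        outer(py, montage$positions[, 2], "-")^2
  wt <- matrix(0, H * W, nch)
  for (p in which(inside)) {
    nn <- order(d2[p, ])[seq_len(k)]
    w <- 1 / (d2[p, nn] + 1e-12)
    wt[p, nn] <- w / sum(w)
  }
  list(weights = wt, inside = inside, H = H, W = W)
}

#' Project per-channel values onto a 2D topographic map
#'
#' Interpolates one scalar per electrode onto an H x W head-plane image with
#' inverse-distance weighting (see [topomap_weights()]). Within the
#' electrode hull every pixel is a convex combination of channel values, so
#' `min(values) <= pixel <= max(values)`; pixels outside the unit disc are 0.
#'
#' @param values Numeric vector, one value per montage channel.
#' @param montage A `montage`.
#' @param H,W Grid size (default 32 x 32; powers of two so a single Haar
#'   level halves them exactly).
#' @param weights Optional precomputed [topomap_weights()] for repeated
#'   projections.
#' @return H x W numeric matrix (row 1 = front of the head).
#' @export
project_topomap <- function(values, montage, H = 32, W = 32, weights = NULL) {
  if (length(values) != length(montage$channel_names)) {
    stop("length(values) = ", length(values), " but montage has ",
         length(montage$channel_names), " channels")
  }
  if (is.null(weights)) weights <- topomap_weights(montage, H, W)
  v <- as.vector(weights$weights %*% values)
  v[!weights$inside] <- 0
  matrix(v, weights$H, weights$W, byrow = TRUE)
}

#' Encode a topographic map over SNN simulation time steps
#'
#' Default `"direct"` encoding repeats the map at every time step
#' (constant-current input; the first spiking layer converts it into spike
#' trains implicitly) and is fully deterministic. `"poisson"` rate coding
#' instead draws an independent Bernoulli spike map per time step with
#' per-pixel probability given by the min-max normalized map.
#'
#' @param map H x W numeric matrix; H and W must be powers of two so that
#'   a single Haar level halves the grid exactly.
#' @param T_steps Number of simulation time steps (>= 1).
#' @param C Number of input feature channels (map replicated; default 1).
#' @param label Optional class label attached to the window.
#' @param encoding `"direct"` (default) or `"poisson"`.
#' @return An `encoded_window`: list with `x` (T x C x H x W array) and
#'   `label`.
#' @export
encode_timesteps <- function(map, T_steps = 4, C = 1, label = NA_integer_,
                             encoding = c("direct", "poisson")) {
  encoding <- match.arg(encoding)
  stopifnot(T_steps >= 1, C >= 1)
  H <- nrow(map); W <- ncol(map)
  if (log2(H) %% 1 != 0 || log2(W) %% 1 != 0) {
    stop("map dimensions must be powers of two (Haar halving)")
  }
  x <- array(0, dim = c(T_steps, C, H, W))
  if (encoding == "poisson") {
    rng <- range(map)
    p <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
    for (t in seq_len(T_steps)) for (cc in seq_len(C)) {
      x[t, cc, , ] <- matrix(stats::rbinom(H * W, 1, as.vector(p)), H, W)
    }
  } else {
    for (t in seq_len(T_steps)) for (cc in seq_len(C)) x[t, cc, , ] <- map
  }
  structure(list(x = x, label = label), class = "encoded_window")
}

#' Write a topographic map as a grayscale PNG for inspection
#'
#' Min-max normalizes the map and writes it as an 8-bit grayscale image.
#'
#' @param map H x W numeric matrix (e.g. from [project_topomap()]).
#' @param path Output PNG file.
#' @return `path`, invisibly.
#' @export
write_topomap_png <- function(map, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  rng <- range(map)
  img <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
  png::writePNG(img, path)
  invisible(path)
}

#' Encode decision windows as topographic spike-ready inputs
#'
#' Maps each window to alpha-band channel power, projects it onto an
#' H x W topographic grid, standardizes each map to zero mean and unit
#' variance over in-disc pixels, and replicates it over `T_steps` time
#' steps. This is the bridge from preprocessed EEG to the network input.
#'
#' @param windows List of `eeg_window` (already alpha-band limited).
#' @param montage The recording's `montage`.
#' @param H,W Topographic grid size.
#' @param T_steps SNN simulation time steps.
#' @return An `encoded_dataset`: list with `x` (n x T x 1 x H x W array),
#'   `labels` (integer vector), `H`, `W`, `T`.
#' @export
encode_windows <- function(windows, montage, H = 32, W = 32, T_steps = 4) {
  if (length(windows) == 0) stop("no windows to encode")
  wts <- topomap_weights(montage, H, W)
  n <- length(windows)
  x <- array(0, dim = c(n, T_steps, 1, H, W))
  labels <- integer(n)
  inside <- matrix(wts$inside, H, W, byrow = TRUE)
  for (i in seq_len(n)) {
    map <- project_topomap(channel_power(windows[[i]]), montage, H, W, wts)
    v <- map[inside]
    map[inside] <- (v - mean(v)) / (stats::sd(v) + 1e-8)
    for (t in seq_len(T_steps)) x[i, t, 1, , ] <- map
    labels[i] <- windows[[i]]$label
  }
  structure(list(x = x, labels = labels, H = H, W = W, T = T_steps),
            class = "encoded_dataset")
}
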