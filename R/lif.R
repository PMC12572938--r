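#' Leaky integrate-and-fire neuron constants
#'
#' @param tau Membrane time constant in simulation steps (>= 1; leak factor
#'   is `1 - 1/tau`).
#' @param v_th Firing threshold potential.
#' @param v_reset Reset potential after a spike (hard reset).
#' @param surrogate_alpha Sharpness of the sigmoid surrogate gradient used
#'   during backpropagation.
#' @return An object of class `lif_config`.
#' @export
lif_config <- function(tau = 2, v_th = 0.5, v_reset = 0, surrogate_alpha = 4) {
  if (tau < 1) stop("tau must be >= 1")
  if (v_th <= v_reset) stop("v_th must exceed v_reset")
  if (surrogate_alpha <= 0) stop("surrogate_alpha must be positive")
  structure(list(tau = tau, v_th = v_th, v_reset = v_reset,
                 surrogate_alpha = surrogate_alpha), class = "lif_config")
}

#' Heaviside step function
#'
#' Returns 1 where `u >= 0` and 0 otherwise — the spike generation
#' nonlinearity of the LIF neuron.
#'
#' @param u Numeric array of potential differences.
#' @return Binary array of the same shape.
#' @export
heaviside <- function(u) {
  if (any(!is.finite(u))) stop("heaviside input must be finite")
  (u >= 0) + 0
}

#' One LIF integration step
#'
#' Charges the membrane, `H = V + (X - (V - v_reset)) / tau`, emits a spike
#' where `H - v_th >= 0`, and hard-resets fired neurons to `v_reset`:
#' `V' = H (1 - S) + v_reset S`.
#'
#' @param state List with membrane potential array `v` (or a bare array).
#' @param x Input current, same shape as `state$v`.
#' @param cfg A [lif_config()].
#' @return List with binary `spikes` and the updated `state`.
#' @export
lif_step <- function(state, x, cfg = lif_config()) {
  v <- if (is.list(state)) state$v else state
  if (!all(dim2(v) == dim2(x))) stop("shape mismatch between state and input")
  h <- v + (x - (v - cfg$v_reset)) / cfg$tau
  s <- heaviside(h - cfg$v_th)
  v_new <- h * (1 - s) + cfg$v_reset * s
  list(spikes = s, state = list(v = v_new), h = h)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Run a LIF neuron (layer) over a spike-train of inputs
#'
#' Folds [lif_step()] over the leading time axis with an initial membrane
#' potential (0 by default). Accepts a T-length vector (single neuron), a
#' T x N matrix, or a T x ... array; the output spike train has the same
#' shape and is strictly binary.
#'
#' @param x_seq Input currents with time as the first axis.
#' @param cfg A [lif_config()].
#' @param initial_v Initial membrane potential (scalar or array).
#' @return Binary array of spikes, same shape as `x_seq`.
#' @export
lif_sequence <- function(x_seq, cfg = lif_config(), initial_v = 0) {
  d <- dim2(x_seq)
  x <- if (is.null(dim(x_seq))) matrix(x_seq, ncol = 1) else
    matrix(x_seq, nrow = d[1])
  T_steps <- nrow(x)
  v <- matrix(initial_v, 1, ncol(x))
  out <- matrix(0, T_steps, ncol(x))
  for (t in seq_len(T_steps)) {
    st <- lif_step(list(v = v), matrix(x[t, ], 1), cfg)
    out[t, ] <- st$spikes
    v <- st$state$v
  }
  if (is.null(dim(x_seq))) as.vector(out) else array(out, dim = d)
}

#' Sigmoid surrogate gradient of the Heaviside function
#'
#' The backward-pass stand-in for the Heaviside derivative:
#' `g(u) = alpha * sigma(alpha u) * (1 - sigma(alpha u))` with
#' `sigma(z) = 1 / (1 + exp(-z))`. The forward pass remains the exact
#' Heaviside; this derivative-of-a-sharpened-sigmoid form is the standard
#' reading of "sigmoid surrogate" in surrogate-gradient training.
#'
#' @param u Pre-threshold values (`H - v_th`).
#' @param alpha Sharpness (default 4).
#' @return Gradient values, same shape as `u`; peaks at `alpha / 4` at
#'   `u = 0` and vanishes for large `|u|`.
#' @export
surrogate_gradient <- function(u, alpha = 4) {
  s <- 1 / (1 + exp(-alpha * u))
  alpha * s * (1 - s)
}
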