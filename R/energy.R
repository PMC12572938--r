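#' Measure spiking rates of a model on a dataset
#'
#' Runs an instrumented forward pass over the dataset and accumulates, for
#' every LIF layer, the fraction of spike-tensor entries equal to 1 over
#' all windows and time steps, plus the element-weighted global rate.
#'
#' @param model A `spikewav_model`.
#' @param data An `encoded_dataset`.
#' @param batch_size Forward batch size.
#' @return List with `per_layer` (named rates in `[0, 1]`), `global_rate`,
#'   and `time_steps`.
#' @export
measure_spike_rate <- function(model, data, batch_size = 32) {
  n <- length(data$labels)
  acc_num <- NULL; acc_den <- NULL; nms <- NULL
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    scores <- model_forward(model, subset_encoded(data, idx), record = TRUE)
    sp <- attr(scores, "spikes")
    if (is.null(nms)) {
      nms <- sp$names
      acc_num <- numeric(length(nms)); acc_den <- numeric(length(nms))
    }
    acc_num <- acc_num + sp$rates * sp$counts
    acc_den <- acc_den + sp$counts
  }
  if (is.null(nms) || length(nms) == 0) stop("no spiking layers found")
  per_layer <- acc_num / acc_den
  names(per_layer) <- nms
  list(per_layer = per_layer, global_rate = sum(acc_num) / sum(acc_den),
       time_steps = model$cfg$T)
}

#' Energy-consumption ratio of the SNN relative to its ANN counterpart
#'
#' The neuromorphic energy model counts one accumulate (AC) per spike per
#' time step in the SNN against one multiply-accumulate (MAC) per connection
#' in the equivalent ANN:
#' `energy_rate = ac_over_mac * rate * time_steps`, and the efficiency
#' factor is its reciprocal. The default per-operation ratio is 1/17 (an
#' accumulate is 17x cheaper than a multiply-accumulate).
#'
#' @param rate Average spiking rate in `[0, 1]`.
#' @param time_steps SNN simulation time steps.
#' @param ac_over_mac Per-operation AC:MAC energy ratio.
#' @return An `energy_report` list with `energy_rate`, `efficiency`,
#'   `spiking_rate`, `time_steps`, `ac_over_mac`. A zero rate yields an
#'   infinite-efficiency sentinel with a warning.
#' @export
energy_rate <- function(rate, time_steps = 4, ac_over_mac = 1 / 17) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (time_steps < 1) stop("time_steps must be >= 1")
  if (ac_over_mac <= 0) stop("ac_over_mac must be positive")
  er <- ac_over_mac * rate * time_steps
  if (rate == 0) {
    warning("zero spiking rate: efficiency reported as +Inf")
    eff <- Inf
  } else {
    eff <- 1 / er
  }
  structure(list(energy_rate = er, efficiency = eff, spiking_rate = rate,
                 time_steps = time_steps, ac_over_mac = ac_over_mac),
            class = "energy_report")
}

#' Full energy report for a model on a dataset
#'
#' Combines [measure_spike_rate()] and [energy_rate()].
#'
#' @param model A `spikewav_model`.
#' @param data An `encoded_dataset`.
#' @param ac_over_mac Per-operation AC:MAC energy ratio.
#' @return An `energy_report` with the additional element `per_layer_rate`.
#' @export
energy_report <- function(model, data, ac_over_mac = 1 / 17) {
  sr <- measure_spike_rate(model, data)
  rep <- energy_rate(sr$global_rate, sr$time_steps, ac_over_mac)
  rep$per_layer_rate <- sr$per_layer
  rep
}

#' @export
print.energy_report <- function(x, ...) {
  cat("Energy report (SNN vs ANN counterpart)\n")
  cat(sprintf("  spiking rate : %.4f\n", x$spiking_rate))
  cat(sprintf("  time steps   : %d\n", x$time_steps))
  cat(sprintf("  AC/MAC ratio : %.5f\n", x$ac_over_mac))
  cat(sprintf("  energy rate  : %.5f\n", x$energy_rate))
  cat(sprintf("  efficiency   : %.2fx\n", x$efficiency))
  if (!is.null(x$per_layer_rate)) {
    cat("  per-layer spiking rates:\n")
    for (nm in names(x$per_layer_rate)) {
      cat(sprintf("    %-12s %.4f\n", nm, x$per_layer_rate[[nm]]))
    }
  }
  invisible(x)
}
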