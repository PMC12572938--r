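#' Training configuration
#'
#' @param lr Adam learning rate (paper setting: 1e-4 for full-scale
#'   training; the desk-scale benchmark uses 1e-3, see
#'   [run_lateralized_benchmark()]).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param seed RNG seed governing initialization order-independent epoch
#'   shuffling and the validation split.
#' @param lambda_l1 Weight of the optional L1 penalty on the learned
#'   wavelet filter coefficients (0 disables the term).
#' @param optimizer Only `"adam"` is implemented.
#' @param val_fraction Fraction of the training set held out (stratified)
#'   for the per-epoch validation accuracy in the history.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 30, batch_size = 16, seed = 1L,
                         lambda_l1 = 0, optimizer = "adam",
                         val_fraction = 0.2) {
  if (lr <= 0) stop("lr must be positive")
  if (epochs < 1) stop("epochs must be >= 1")
  if (lambda_l1 < 0) stop("lambda_l1 must be >= 0")
  if (optimizer != "adam") stop("only the adam optimizer is implemented")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 lambda_l1 = lambda_l1, optimizer = optimizer,
                 val_fraction = val_fraction), class = "train_config")
}

#' Cross-entropy training loss with optional wavelet-coefficient sparsity
#'
#' Mean softmax cross-entropy of the class scores plus
#' `lambda_l1 * sum(abs(wavelet_coeffs))` when `lambda_l1 > 0`.
#'
#' @param scores B x n_classes score matrix.
#' @param labels Integer labels, 0-based.
#' @param wavelet_coeffs Optional numeric vector/array of learned wavelet
#'   filter coefficients entering the L1 term.
#' @param lambda_l1 L1 weight.
#' @return Scalar loss.
#' @export
swf_loss <- function(scores, labels, wavelet_coeffs = NULL, lambda_l1 = 0) {
  if (!all(is.finite(scores))) stop("scores must be finite")
  B <- nrow(scores)
  if (any(labels < 0 | labels >= ncol(scores))) {
    stop("label out of range [0, ", ncol(scores) - 1, "]")
  }
  m <- apply(scores, 1, max)
  lse <- m + log(rowSums(exp(scores - m)))
  ce <- mean(lse - scores[cbind(seq_len(B), labels + 1L)])
  if (lambda_l1 > 0 && !is.null(wavelet_coeffs)) {
    ce <- ce + lambda_l1 * sum(abs(wavelet_coeffs))
  }
  ce
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- as.numeric(g)
    if (!is.null(dim(params[[nm]]))) dim(g) <- dim(params[[nm]])
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

subset_encoded <- function(data, idx) {
  structure(list(x = data$x[idx, , , , , drop = FALSE],
                 labels = data$labels[idx], H = data$H, W = data$W,
                 T = data$T), class = "encoded_dataset")
}

#' Train a spiking wavelet transformer
#'
#' Mini-batch Adam on the cross-entropy objective with surrogate-gradient
#' backpropagation through time. Fully reproducible for a fixed (seed,
#' dataset, config) on a single thread: epoch shuffling and the stratified
#' train/validation split come from a dedicated RNG stream derived from
#' `cfg$seed`. Batch-norm running statistics are updated during training and
#' used for evaluation.
#'
#' @param model A [spikewav_model()].
#' @param data An `encoded_dataset` (see [encode_windows()]).
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with the trained `model` and `history` (a data.frame with
#'   per-epoch train loss, train accuracy, validation accuracy and mean
#'   spiking rate).
#' @export
train_spikewavformer <- function(model, data, cfg = train_config(),
                                 verbose = FALSE) {
  n <- length(data$labels)
  if (n == 0) stop("empty dataset")
  set.seed(derive_seed(cfg$seed, 101L))
  val_idx <- integer(0)
  if (cfg$val_fraction > 0) {
    for (cl in unique(data$labels)) {
      ic <- which(data$labels == cl)
      val_idx <- c(val_idx, sample(ic, max(1, round(cfg$val_fraction *
                                                      length(ic)))))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  ccfg <- cfg_for_cpp(model$cfg)
  opt <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0),
                     spike_rate = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    set.seed(derive_seed(cfg$seed, 1000L + ep))
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_correct <- 0; ep_rate <- 0; n_batch <- 0
    for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
      xb <- data$x[idx, , , , , drop = FALSE]
      yb <- as.integer(data$labels[idx])
      step <- cpp_fwd_bwd(model$params, model$state, ccfg, batch_to_mat(xb),
                          length(idx), yb, cfg$lambda_l1, FALSE)
      if (!is.finite(step$loss)) {
        stop("NaN/Inf loss at epoch ", ep, ", batch ", n_batch + 1,
             " (lr = ", cfg$lr, "); aborting")
      }
      model$state <- step$state
      upd <- adam_step(model$params, step$grads, opt, cfg$lr)
      model$params <- upd$params
      opt <- upd$opt
      ep_loss <- ep_loss + step$loss * length(idx)
      pred <- apply(step$logits, 1, which.max) - 1L
      ep_correct <- ep_correct + sum(pred == yb)
      ep_rate <- ep_rate + step$spike_rate
      n_batch <- n_batch + 1
    }
    val_acc <- NA_real_
    if (length(val_idx) > 0) {
      val_acc <- evaluate_model(model, subset_encoded(data, val_idx))$accuracy
    }
    hist <- rbind(hist, data.frame(
      epoch = ep, train_loss = ep_loss / length(ord),
      train_acc = ep_correct / length(ord), val_acc = val_acc,
      spike_rate = ep_rate / max(1, n_batch)))
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  train acc %.3f  val acc %s  spike rate %.3f",
        ep, hist$train_loss[ep], hist$train_acc[ep],
        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc)),
        hist$spike_rate[ep]))
    }
  }
  list(model = model, history = hist)
}

#' Evaluate a model on a labeled dataset
#'
#' @param model A `spikewav_model`.
#' @param data An `encoded_dataset`.
#' @param batch_size Evaluation batch size.
#' @return List with `accuracy`, `per_class` (named accuracy per label),
#'   and `spike_rate` (mean spiking rate over the evaluation pass).
#' @export
evaluate_model <- function(model, data, batch_size = 32) {
  n <- length(data$labels)
  if (n == 0) stop("empty dataset")
  preds <- integer(n)
  rate_num <- 0; rate_den <- 0
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    scores <- model_forward(model, subset_encoded(data, idx), record = TRUE)
    preds[idx] <- apply(scores, 1, which.max) - 1L
    sp <- attr(scores, "spikes")
    rate_num <- rate_num + sum(sp$rates * sp$counts)
    rate_den <- rate_den + sum(sp$counts)
  }
  labs <- as.integer(data$labels)
  per_class <- vapply(sort(unique(labs)), function(cl) {
    mean(preds[labs == cl] == cl)
  }, numeric(1))
  names(per_class) <- sort(unique(labs))
  list(accuracy = mean(preds == labs), per_class = per_class,
       spike_rate = rate_num / max(1, rate_den))
}
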