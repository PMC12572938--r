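test_that("the loss is cross-entropy with an optional wavelet L1 term", {
  # confident correct scores drive the loss toward zero
  sc <- matrix(c(20, -20, -20, 20), 2, byrow = TRUE)
  expect_lt(swf_loss(sc, c(0L, 1L)), 1e-8)
  # uniform scores over 2 classes: ln 2
  expect_equal(swf_loss(matrix(0, 3, 2), c(0L, 1L, 0L)), log(2),
               tolerance = 1e-12)
  w <- c(-1, 2, 0.5)
  expect_equal(swf_loss(matrix(0, 1, 2), 0L, w, 0),
               swf_loss(matrix(0, 1, 2), 0L))
  expect_equal(swf_loss(matrix(0, 1, 2), 0L, w, 0.1),
               log(2) + 0.1 * 3.5, tolerance = 1e-12)
  expect_error(swf_loss(matrix(0, 1, 2), 5L), "out of range")
})

test_that("one epoch on a tiny set runs and records history", {
  cfg <- tiny_cfg(L = 1)
  m <- spikewav_model(cfg, seed = 9)
  ds <- rand_encoded(8, cfg, seed = 34)
  fit <- train_spikewavformer(m, ds, train_config(lr = 1e-3, epochs = 1,
                                                  batch_size = 4, seed = 1))
  expect_equal(nrow(fit$history), 1)
  expect_true(is.finite(fit$history$train_loss))
  expect_true(fit$history$spike_rate > 0 && fit$history$spike_rate < 1)
})

test_that("training is reproducible for a fixed seed and sensitive to it", {
  cfg <- tiny_cfg(L = 1)
  ds <- rand_encoded(16, cfg, seed = 35)
  run <- function(seed) {
    m <- spikewav_model(cfg, seed = 10)
    train_spikewavformer(m, ds, train_config(lr = 1e-3, epochs = 2,
                                             batch_size = 8, seed = seed))
  }
  f1 <- run(1); f2 <- run(1); f3 <- run(2)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("the loss decreases on a separable lateralized task", {
  # tiny version of the benchmark task: fewer trials, tiny model
  spec <- synth_spec(n_channels = 8, trial_length_s = 4,
                     n_trials_per_class = 8, seed = 21)
  rec <- preprocess_recording(generate_dataset(spec), preproc_config())
  wins <- segment_windows(extract_band(rec, 8, 13), preproc_config())
  enc <- encode_windows(wins, rec$montage, H = 8, W = 8, T_steps = 2)
  m <- spikewav_model(tiny_cfg(L = 1), seed = 11)
  fit <- train_spikewavformer(m, enc, train_config(lr = 1e-3, epochs = 8,
                                                   batch_size = 8, seed = 3,
                                                   val_fraction = 0))
  sm <- stats::filter(fit$history$train_loss, rep(1 / 3, 3), sides = 1)
  expect_lt(sm[length(sm)], sm[3])
})

test_that("surrogate backprop matches finite differences on a two-neuron toy", {
  # relaxed network: linear(2 -> 2) -> LIF over T -> time-sum -> head -> CE.
  # In relaxed mode the spike is a sharpened sigmoid and the reset is
  # differentiated exactly, so finite differences probe the same function
  # the backward pass differentiates.
  tau <- 2; vth <- 0.5; vr <- 0; al <- 4
  T_steps <- 3
  set.seed(36)
  x <- matrix(rnorm(T_steps * 2), T_steps, 2)
  W1 <- matrix(rnorm(4, sd = 1), 2, 2)
  W2 <- matrix(rnorm(4, sd = 1), 2, 2)
  y <- 1L

  fwd <- function(W1, W2) {
    v <- c(0, 0); ssum <- c(0, 0)
    Hs <- matrix(0, T_steps, 2); Ss <- matrix(0, T_steps, 2)
    for (t in 1:T_steps) {
      z <- as.vector(x[t, ] %*% W1)
      h <- v + (z - (v - vr)) / tau
      s <- 1 / (1 + exp(-al * (h - vth)))
      v <- h * (1 - s) + vr * s
      Hs[t, ] <- h; Ss[t, ] <- s
      ssum <- ssum + s
    }
    logits <- as.vector(ssum %*% W2)
    p <- exp(logits - max(logits)); p <- p / sum(p)
    list(loss = -log(p[y + 1]), p = p, H = Hs, S = Ss, ssum = ssum)
  }

  f <- fwd(W1, W2)
  dlogit <- f$p; dlogit[y + 1] <- dlogit[y + 1] - 1
  dW2 <- outer(f$ssum, dlogit)
  dssum <- as.vector(W2 %*% dlogit)
  gV <- c(0, 0); dW1 <- matrix(0, 2, 2)
  for (t in T_steps:1) {
    h <- f$H[t, ]; s <- f$S[t, ]
    surr <- al * s * (1 - s)
    gH <- (dssum - gV * (h - vr)) * surr + gV * (1 - s)
    dz <- gH / tau
    dW1 <- dW1 + outer(x[t, ], dz)
    gV <- gH * (1 - 1 / tau)
  }

  h <- 1e-6
  for (idx in 1:4) {
    for (which_w in 1:2) {
      Wp <- list(W1, W2); Wm <- list(W1, W2)
      Wp[[which_w]][idx] <- Wp[[which_w]][idx] + h
      Wm[[which_w]][idx] <- Wm[[which_w]][idx] - h
      fd <- (fwd(Wp[[1]], Wp[[2]])$loss - fwd(Wm[[1]], Wm[[2]])$loss) / (2 * h)
      an <- if (which_w == 1) dW1[idx] else dW2[idx]
      expect_equal(an, fd, tolerance = 1e-3)
    }
  }
})

test_that("full-network relaxed backprop matches finite differences", {
  cfg <- tiny_cfg()
  m <- spikewav_model(cfg, seed = 12)
  ds <- rand_encoded(2, cfg, seed = 37)
  X0 <- spikewavformer:::batch_to_mat(ds$x)
  ccfg <- spikewavformer:::cfg_for_cpp(cfg)
  labs <- c(0L, 1L)
  res <- spikewavformer:::cpp_fwd_bwd(m$params, m$state, ccfg, X0, 2, labs,
                                      0, TRUE)
  h <- 1e-5
  set.seed(38)
  for (nm in c("blk1_wq", "blk1_wav", "blk2_wf", "sps_conv1", "head_W",
               "blk2_bn1_g")) {
    g <- as.numeric(res$grads[[nm]])
    for (i in sample(length(m$params[[nm]]), 3)) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (spikewavformer:::cpp_fwd_bwd(pp, m$state, ccfg, X0, 2, labs,
                                          0, TRUE)$loss -
             spikewavformer:::cpp_fwd_bwd(pm, m$state, ccfg, X0, 2, labs,
                                          0, TRUE)$loss) / (2 * h)
      denom <- max(abs(fd), abs(g[i]), 1e-6)
      expect_lt(abs(fd - g[i]) / denom, 1e-3)
    }
  }
})

test_that("the wavelet L1 penalty adds lambda * sign(W) to the filter gradient", {
  cfg <- tiny_cfg(L = 1)
  m <- spikewav_model(cfg, seed = 13)
  # perturb the filter so signs are informative
  set.seed(39)
  m$params$blk1_wav <- m$params$blk1_wav +
    array(rnorm(length(m$params$blk1_wav), sd = 0.1),
          dim = dim(m$params$blk1_wav))
  ds <- rand_encoded(4, cfg, seed = 39)
  X0 <- spikewavformer:::batch_to_mat(ds$x)
  ccfg <- spikewavformer:::cfg_for_cpp(cfg)
  labs <- as.integer(ds$labels)
  r0 <- spikewavformer:::cpp_fwd_bwd(m$params, m$state, ccfg, X0, 4, labs,
                                     0, FALSE)
  lam <- 0.05
  r1 <- spikewavformer:::cpp_fwd_bwd(m$params, m$state, ccfg, X0, 4, labs,
                                     lam, FALSE)
  expect_equal(as.numeric(r1$grads$blk1_wav),
               as.numeric(r0$grads$blk1_wav) +
                 lam * sign(as.numeric(m$params$blk1_wav)),
               tolerance = 1e-12)
  expect_equal(r1$loss, r0$loss + lam * sum(abs(m$params$blk1_wav)),
               tolerance = 1e-10)
  # lambda = 0 reduces to pure cross-entropy
  expect_identical(r0$loss, spikewavformer:::cpp_fwd_bwd(
    m$params, m$state, ccfg, X0, 4, labs, 0, FALSE)$loss)
})

test_that("evaluation reports accuracy, per-class accuracy and their identity", {
  cfg <- tiny_cfg(L = 1)
  m <- spikewav_model(cfg, seed = 14)
  ds <- rand_encoded(20, cfg, seed = 40)
  ev <- evaluate_model(m, ds)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  labs <- as.integer(ds$labels)
  w <- as.vector(table(labs)) / length(labs)
  expect_equal(sum(ev$per_class * w), ev$accuracy, tolerance = 1e-12)
  expect_true(ev$spike_rate > 0 && ev$spike_rate < 1)
  # an untrained model on balanced labels sits near chance
  expect_lt(abs(ev$accuracy - 0.5), 0.35)
  expect_error(evaluate_model(m, subset_ds(ds, integer(0))), "empty")
})
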