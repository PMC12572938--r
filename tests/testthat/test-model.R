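test_that("SPS produces binary tokens of the configured shape", {
  cfg <- tiny_cfg()
  m <- spikewav_model(cfg, seed = 1)
  set.seed(27)
  x <- array(rnorm(cfg$T * 1 * 8 * 8), dim = c(cfg$T, 1, 8, 8))
  toks <- sps(m, x)
  expect_equal(dim(toks), c(cfg$T, cfg$patch_grid^2, cfg$d))
  expect_true(all(toks %in% c(0, 1)))
  zero <- sps(m, array(0, dim = dim(x)))
  expect_true(all(zero == 0))
})

test_that("the desk-scale shape contract holds: 32x32 maps, 4x4 tokens, d = 32", {
  m <- spikewav_model(desk_model_config(), seed = 1)
  set.seed(28)
  x <- array(rnorm(4 * 1 * 32 * 32), dim = c(4, 1, 32, 32))
  toks <- sps(m, x)
  expect_equal(dim(toks), c(4, 16, 32))
})

test_that("the MLP block preserves shape and binarity", {
  cfg <- tiny_cfg()
  m <- spikewav_model(cfg, seed = 2)
  x <- array(rbinom(2 * 4 * 8, 1, 0.5), dim = c(2, 4, 8))
  blk <- list(w1 = m$params$blk1_w1, w2 = m$params$blk1_w2,
              bn1_g = m$params$blk1_bn1_g, bn1_b = m$params$blk1_bn1_b,
              bn1_m = m$state$blk1_bn1_m, bn1_v = m$state$blk1_bn1_v,
              bn2_g = m$params$blk1_bn2_g, bn2_b = m$params$blk1_bn2_b,
              bn2_m = m$state$blk1_bn2_m, bn2_v = m$state$blk1_bn2_v)
  out <- mlp_block(x, blk, cfg$lif)
  expect_equal(dim(out), dim(x))
  expect_true(all(out %in% c(0, 1)))
  expect_true(all(mlp_block(array(0, dim = dim(x)), blk, cfg$lif) == 0))
})

test_that("forward yields finite per-class scores and deterministic repeats", {
  cfg <- tiny_cfg()
  m <- spikewav_model(cfg, seed = 3)
  ds <- rand_encoded(4, cfg, seed = 29)
  s1 <- model_forward(m, ds)
  expect_equal(dim(s1), c(4, cfg$n_classes))
  expect_true(all(is.finite(s1)))
  s2 <- model_forward(m, ds)
  expect_identical(s1[, ], s2[, ])  # membrane state fully reset per call

  # identical inputs in one batch give identical score rows
  ds$x[2, , , , ] <- ds$x[1, , , , ]
  s3 <- model_forward(m, ds)
  expect_equal(s3[1, ], s3[2, ], tolerance = 1e-12)
})

test_that("compiled and reference forward passes agree exactly", {
  for (wav in c(TRUE, FALSE)) {
    cfg <- tiny_cfg(wavelet_enabled = wav)
    m <- spikewav_model(cfg, seed = 4)
    ds <- rand_encoded(3, cfg, seed = 30)
    expect_equal(model_forward(m, ds, engine = "cpp")[, ],
                 model_forward(m, ds, engine = "r")[, ], tolerance = 1e-12)
  }
})

test_that("simulation depth matters: T = 1 and T = 4 score differently", {
  cfg1 <- model_config(T_steps = 1, L = 1, d = 8, patch_grid = 2,
                       mlp_ratio = 2, heads = 2, map_hw = 8)
  cfg4 <- model_config(T_steps = 4, L = 1, d = 8, patch_grid = 2,
                       mlp_ratio = 2, heads = 2, map_hw = 8)
  m1 <- spikewav_model(cfg1, seed = 5)
  m4 <- spikewav_model(cfg4, seed = 5)  # identical weights (same seed/cfg sizes)
  for (nm in names(m1$params)) m4$params[[nm]] <- m1$params[[nm]]
  set.seed(31)
  map <- matrix(rnorm(64), 8, 8)
  x1 <- array(0, dim = c(1, 1, 1, 8, 8)); x1[1, 1, 1, , ] <- map
  x4 <- array(0, dim = c(1, 4, 1, 8, 8))
  for (t in 1:4) x4[1, t, 1, , ] <- map
  expect_false(isTRUE(all.equal(model_forward(m1, x1)[1, ],
                                model_forward(m4, x4)[1, ])))
})

test_that("prediction takes the argmax with ties broken toward the lower class", {
  expect_equal(which.max(c(0.2, 0.9)) - 1L, 1L)
  expect_equal(which.max(c(0.5, 0.5)) - 1L, 0L)
  cfg <- tiny_cfg()
  m <- spikewav_model(cfg, seed = 6)
  ds <- rand_encoded(5, cfg, seed = 32)
  labs <- predict(m, ds)
  expect_length(labs, 5)
  expect_true(all(labs %in% c(0L, 1L)))
  sc <- model_forward(m, ds)
  expect_equal(labs, apply(sc, 1, which.max) - 1L)
})

test_that("parameter counts are deterministic from the configuration", {
  m1 <- spikewav_model(tiny_cfg(), seed = 1)
  m2 <- spikewav_model(tiny_cfg(), seed = 99)
  expect_equal(n_params(m1), n_params(m2))
  m_off <- spikewav_model(tiny_cfg(wavelet_enabled = FALSE), seed = 1)
  expect_lt(n_params(m_off), n_params(m1))
  # rebuilding with the same seed reproduces the weights exactly
  m3 <- spikewav_model(tiny_cfg(), seed = 1)
  expect_identical(m1$params, m3$params)
})

test_that("ablating the wavelet branch reproduces a plain spiking-attention encoder", {
  cfg_off <- tiny_cfg(wavelet_enabled = FALSE)
  m <- spikewav_model(cfg_off, seed = 7)
  ds <- rand_encoded(2, cfg_off, seed = 33)
  # compiled ablated model vs the reference per-operation pipeline
  sc_cpp <- model_forward(m, ds, engine = "cpp")
  sc_r <- model_forward(m, ds, engine = "r")
  expect_equal(sc_cpp[, ], sc_r[, ], tolerance = 1e-12)

  # block-level: the recorded attention projection is the block output
  logits <- model_forward(m, subset_ds(ds, 1), record = TRUE, engine = "r")
  rec <- attr(logits, "spikes")
  x1 <- array(ds$x[1, , , , , drop = FALSE], dim = dim(ds$x)[-1])
  toks <- sps(m, x1)
  p <- list(d = cfg_off$d, heads = cfg_off$heads, scale_s = cfg_off$scale_s,
            wavelet_enabled = FALSE,
            wq = m$params$blk1_wq, wk = m$params$blk1_wk,
            wv = m$params$blk1_wv, wo = m$params$blk1_wo)
  for (nm in c("bnq", "bnk", "bnv", "bno")) {
    p[[paste0(nm, "_g")]] <- m$params[[paste0("blk1_", nm, "_g")]]
    p[[paste0(nm, "_b")]] <- m$params[[paste0("blk1_", nm, "_b")]]
    p[[paste0(nm, "_m")]] <- m$state[[paste0("blk1_", nm, "_m")]]
    p[[paste0(nm, "_v")]] <- m$state[[paste0("blk1_", nm, "_v")]]
  }
  ssa <- swsa_block(toks, p, cfg_off$lif)
  expect_equal(spikewavformer:::tokens_to_mat(ssa), rec$blk1_proj,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("input shape mismatches raise a descriptive error", {
  m <- spikewav_model(tiny_cfg(), seed = 8)
  bad <- array(0, dim = c(1, 3, 1, 8, 8))  # wrong T
  expect_error(model_forward(m, bad), "does not match model config")
})
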