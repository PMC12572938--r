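test_that("channel power is the mean squared amplitude", {
  zero <- make_window(matrix(0, 3, 64))
  expect_equal(channel_power(zero), rep(0, 3))
  win <- make_window(rbind(sine_wave(10, 128, 1280),
                           2 * sine_wave(10, 128, 1280)))
  p <- channel_power(win)
  expect_equal(p[1], 0.5, tolerance = 0.01)   # mean of sin^2
  expect_equal(p[2] / p[1], 4, tolerance = 1e-9)
  expect_error(channel_power(make_window(matrix(0, 2, 0))), "empty")
})

test_that("projection is a convex interpolation anchored at the electrodes", {
  m <- make_montage(32)
  wts <- topomap_weights(m, 32, 32)
  inside <- matrix(wts$inside, 32, 32, byrow = TRUE)

  const <- project_topomap(rep(3.7, 32), m, weights = wts)
  expect_equal(const[inside], rep(3.7, sum(inside)), tolerance = 1e-9)
  expect_true(all(const[!inside] == 0))

  # one hot channel among zeros peaks at the grid cell nearest the electrode
  for (hot in c(3L, 17L, 30L)) {
    v <- rep(0, 32); v[hot] <- 1
    map <- project_topomap(v, m, weights = wts)
    peak <- which(map == max(map), arr.ind = TRUE)[1, ]
    gx <- seq(-1, 1, length.out = 32)[peak["col"]]
    gy <- seq(1, -1, length.out = 32)[peak["row"]]
    d_all <- sqrt((m$positions[, 1] - gx)^2 + (m$positions[, 2] - gy)^2)
    expect_equal(which.min(d_all), hot, ignore_attr = TRUE)
    expect_true(all(map >= 0 & map <= 1))
  }
  expect_error(project_topomap(rep(1, 5), m), "channels")
})

test_that("left-heavy alpha power lateralizes the map", {
  m <- make_montage(32)
  hemi <- channel_hemisphere(m$channel_names)
  v <- ifelse(hemi == "left", 2, ifelse(hemi == "right", 0.5, 1.25))
  map <- project_topomap(v, m)
  expect_gt(mean(map[, 1:16]), mean(map[, 17:32]))
})

test_that("projection is linear in the channel values", {
  m <- make_montage(8)
  wts <- topomap_weights(m, 16, 16)
  set.seed(5)
  v1 <- rnorm(8); v2 <- rnorm(8)
  lhs <- project_topomap(2 * v1 - 3 * v2, m, 16, 16, wts)
  rhs <- 2 * project_topomap(v1, m, 16, 16, wts) -
    3 * project_topomap(v2, m, 16, 16, wts)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("mirroring montage and values mirrors the map", {
  m <- make_montage(32)
  set.seed(6)
  v <- runif(32)
  m2 <- m
  m2$positions[, 1] <- -m2$positions[, 1]
  map <- project_topomap(v, m)
  map_mir <- project_topomap(v, m2)
  expect_equal(map_mir, map[, 32:1], tolerance = 1e-8)
})

test_that("time-step encoding replicates the map and a LIF layer breaks the symmetry", {
  map <- matrix(runif(64), 8, 8)
  enc <- encode_timesteps(map, T_steps = 4, label = 1L)
  expect_equal(dim(enc$x), c(4, 1, 8, 8))
  for (t in 1:4) expect_equal(enc$x[t, 1, , ], map)
  one <- encode_timesteps(map, T_steps = 1)
  expect_equal(dim(one$x), c(1, 1, 8, 8))

  # identical input at every step through a stateful LIF: the membrane
  # accumulates, so spike patterns differ across time steps
  cfg <- lif_config()
  x_rep <- matrix(0.7, 4, 64)  # T x neurons, identical input each step
  s <- lif_sequence(x_rep, cfg)
  expect_true(all(s[1, ] == 0) && all(s[2, ] == 1))  # charge then fire
  expect_false(all(apply(s, 2, function(col) length(unique(col)) == 1)))
})

test_that("poisson rate coding emits binary maps with rate following intensity", {
  set.seed(60)
  map <- matrix(runif(16 * 16), 16, 16)
  enc <- encode_timesteps(map, T_steps = 200, encoding = "poisson")
  expect_true(all(enc$x %in% c(0, 1)))
  rates <- apply(enc$x[, 1, , ], c(2, 3), mean)
  rng <- range(map)
  p <- (map - rng[1]) / diff(rng)
  expect_gt(cor(as.vector(rates), as.vector(p)), 0.9)
  expect_error(encode_timesteps(matrix(0, 5, 8)), "powers of two")
})

test_that("topographic maps export as grayscale PNG", {
  map <- project_topomap(runif(8), make_montage(8), 16, 16)
  path <- file.path(withr::local_tempdir(), "map.png")
  write_topomap_png(map, path)
  expect_true(file.exists(path))
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], c(16, 16))
})

test_that("window encoding produces standardized maps with labels", {
  m <- make_montage(8)
  set.seed(7)
  wins <- lapply(1:3, function(i) {
    make_window(matrix(rnorm(8 * 64), 8), label = i %% 2L)
  })
  enc <- encode_windows(wins, m, H = 16, W = 16, T_steps = 2)
  expect_equal(dim(enc$x), c(3, 2, 1, 16, 16))
  expect_equal(enc$labels, c(1L, 0L, 1L))
  inside <- matrix(topomap_weights(m, 16, 16)$inside, 16, 16, byrow = TRUE)
  v <- enc$x[1, 1, 1, , ][inside]
  expect_equal(mean(v), 0, tolerance = 1e-6)
  expect_equal(sd(v), 1, tolerance = 1e-2)
})
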