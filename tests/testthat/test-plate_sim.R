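test_that("colonyRadius follows the lag / linear-growth / cap model", {
  expect_identical(colonyRadius(2, 5, 50, 2000), 0)
  expect_equal(colonyRadius(10, 5, 50, 2000), 250)
  expect_equal(colonyRadius(1000, 5, 50, 2000), 2000)
  expect_error(colonyRadius(-1, 5, 50, 2000), "must be >= 0")
  # non-decreasing in time
  tt <- seq(0, 60, by = 0.5)
  r <- colonyRadius(tt, 4, 35, 900)
  expect_true(all(diff(r) >= 0))
  expect_equal(r[tt < 4], rep(0, sum(tt < 4)))
})

test_that("renderFrame is uniform with no visible objects", {
  cfg <- SimulationConfig(sensor_px = 64L, noise_sd = 0)
  no_obj <- simulatePlate(SimulationConfig(sensor_px = 64L, n_viable = 0L,
                                           n_debris = 0L, noise_sd = 0))$truth
  img <- renderFrame(no_obj, 5, cfg)
  expect_true(all(img == img[1L, 1L]))
  # one viable colony before its lag: still uniform (radius zero)
  obj <- data.frame(object_id = 1L, class = "viable", x_px = 32, y_px = 32,
                    lag_h = 10, rate_um_per_h = 100, r_max_um = 2000,
                    fusion_group = NA_integer_, rim_flag = FALSE)
  img <- renderFrame(obj, 3, cfg)
  expect_true(all(img == img[1L, 1L]))
  expect_error(renderFrame(transform(obj, x_px = 1, y_px = 1), 3, cfg),
               "outside plate")
})

test_that("a debris particle renders as exactly one dark component", {
  cfg <- SimulationConfig(sensor_px = 64L, noise_sd = 0)
  deb <- data.frame(object_id = 1L, class = "debris", x_px = 30, y_px = 35,
                    lag_h = 0, rate_um_per_h = 0,
                    r_max_um = 2 * pixelSizeUm(100, 64),
                    fusion_group = NA_integer_, rim_flag = FALSE)
  img <- renderFrame(deb, 0, cfg)
  fg <- (0.9 - img) >= 0.1
  lab <- flood_label(fg, 8L)
  expect_identical(max(lab), 1L)
  ctr <- which(lab == 1L, arr.ind = TRUE)
  expect_equal(mean(ctr[, 1L]), 35, tolerance = 0.1)
  expect_equal(mean(ctr[, 2L]), 30, tolerance = 0.1)
})

test_that("simulatePlate bookkeeping and determinism", {
  empty <- simulatePlate(SimulationConfig(sensor_px = 64L, n_viable = 0L,
                                          n_debris = 0L, noise_sd = 0))
  expect_identical(nrow(empty$truth), 0L)
  for (f in frames(empty$stack)) expect_true(all(f == f[1L, 1L]))

  cfg <- quick_config(n_viable = 5L, n_debris = 3L, rng_seed = 1L,
                      n_frames = 6L)
  sim <- simulatePlate(cfg)
  expect_identical(nrow(sim$truth), 8L)
  expect_identical(sum(sim$truth$class == "viable"), 5L)
  expect_identical(sim$truth$object_id, 1:8)
  # debris: visible from frame 0, no growth; viable: positive growth
  deb <- sim$truth[sim$truth$class == "debris", ]
  expect_true(all(deb$lag_h == 0) && all(deb$rate_um_per_h == 0))
  expect_true(all(sim$truth$rate_um_per_h[sim$truth$class == "viable"] > 0))

  sim2 <- simulatePlate(cfg)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(frames(sim$stack), frames(sim2$stack))
})

test_that("shadows only deepen over time and debris pixels never change", {
  sim <- simulatePlate(quick_config(n_frames = 10L, rng_seed = 9L))
  fr <- frames(sim$stack)
  for (f in seq_len(length(fr) - 1L))
    expect_true(all(fr[[f + 1L]] <= fr[[f]] + 1e-12))

  deb <- simulatePlate(quick_config(n_viable = 0L, n_debris = 6L,
                                    n_frames = 8L, rng_seed = 2L))
  fr <- frames(deb$stack)
  for (f in seq_len(length(fr) - 1L))
    expect_identical(fr[[f + 1L]], fr[[1L]])
})

test_that("an over-crowded plate raises a capacity error", {
  cfg <- SimulationConfig(sensor_px = 128L, n_viable = 500L, n_debris = 0L,
                          r_max_um = 3000, noise_sd = 0)
  expect_error(simulatePlate(cfg), "too crowded")
})

test_that("frame stack geometry matches the sensor model", {
  sim <- simulatePlate(quick_config(n_frames = 4L))
  expect_identical(nFrames(sim$stack), 4L)
  expect_equal(pixelSize(sim$stack), 1000 * 100 / 512)
  expect_equal(frameTimes(sim$stack), 0:3)
  # default geometry: ~65.1 um pixels
  expect_equal(pixelSizeUm(100, 1536), 65.104, tolerance = 1e-4)
})
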