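test_that("pixelSizeUm reproduces the sensor arithmetic", {
  expect_equal(trunc(pixelSizeUm(100, 1536)), 65)
  expect_equal(pixelSizeUm(100, 1536), 100000 / 1536)
  expect_equal(pixelSizeUm(100, 1000), 100)
  expect_equal(pixelSizeUm(90, 1536), 58.59375)
  expect_error(pixelSizeUm(100, 0), "positive")
  expect_error(pixelSizeUm(100, -3), "positive")
})

test_that("buildPlateMask matches a brute-force pixel loop", {
  g0 <- PlateGeometry(c(50, 50), 0)
  expect_false(any(buildPlateMask(g0, c(100, 100))))
  gall <- full_geometry(20)
  expect_true(all(buildPlateMask(gall, c(20, 20))))

  g <- PlateGeometry(c(50, 50), 10)
  m <- buildPlateMask(g, c(100, 100))
  brute <- matrix(FALSE, 100, 100)
  for (r in 1:100) for (cc in 1:100)
    brute[r, cc] <- (r - 50)^2 + (cc - 50)^2 <= 100
  expect_identical(m, brute)
  expect_error(buildPlateMask(PlateGeometry(c(30, 30), 5), c(20, 20)),
               "exceeds image bounds")
})

test_that("estimateBackground is the median inside the plate", {
  g <- full_geometry(4)
  expect_equal(estimateBackground(matrix(0.9, 4, 4), g), 0.9)
  img <- matrix(0.9, 40, 40)
  img[1:3, 1:3] <- 0.2   # < 1% dark pixels do not move the median
  expect_equal(estimateBackground(img, full_geometry(40)), 0.9)
  # checkerboard: even split, median() averages the middle pair
  chk <- matrix(rep(c(0.4, 0.8), 8), 4, 4)
  expect_equal(estimateBackground(chk, g),
               median(sort(as.vector(chk))))  # sort-based oracle: 0.6
  expect_equal(estimateBackground(chk, g), 0.6)
  expect_error(estimateBackground(matrix(0.9, 4, 4),
                                  PlateGeometry(c(2, 2), 0)),
               "empty")
})

test_that("segmentFrame finds thresholded components down to one pixel", {
  g <- full_geometry(20)
  p <- SegmentationParams()
  none <- segmentFrame(matrix(0.9, 20, 20), 0.9, p, g)
  expect_identical(nrow(none$table), 0L)

  one <- segmentFrame(dark_pixels(20, cbind(7, 9), depth = 0.3), 0.9, p, g)
  expect_identical(nrow(one$table), 1L)
  expect_identical(one$table$area_px, 1L)
  expect_equal(c(one$table$row, one$table$col), c(7, 9))

  # below the depth threshold: nothing
  faint <- segmentFrame(dark_pixels(20, cbind(7, 9), depth = 0.05), 0.9, p, g)
  expect_identical(nrow(faint$table), 0L)
})

test_that("segmentFrame agrees with the flood-fill oracle on two squares", {
  img <- matrix(0.9, 30, 30)
  img[5:7, 5:7] <- 0.3
  img[5:7, 12:14] <- 0.3    # separated by >= 2 background columns
  g <- full_geometry(30)
  seg <- segmentFrame(img, 0.9, SegmentationParams(), g)
  expect_identical(nrow(seg$table), 2L)
  expect_identical(seg$table$area_px, c(9L, 9L))
  expect_equal(seg$table$row, c(6, 6))
  expect_equal(sort(seg$table$col), c(6, 13))
  oracle <- flood_label((0.9 - img) >= 0.1, 8L)
  expect_identical(max(oracle), 2L)
  expect_identical(sum(seg$labels > 0L), sum(oracle > 0L))
})

test_that("connectivity setting controls diagonal merging, matching the oracle", {
  img <- dark_pixels(12, rbind(c(4, 4), c(5, 5), c(6, 6)), depth = 0.4)
  g <- full_geometry(12)
  s8 <- segmentFrame(img, 0.9, SegmentationParams(connectivity = 8L), g)
  s4 <- segmentFrame(img, 0.9, SegmentationParams(connectivity = 4L), g)
  expect_identical(nrow(s8$table), max(flood_label((0.9 - img) >= 0.1, 8L)))
  expect_identical(nrow(s4$table), max(flood_label((0.9 - img) >= 0.1, 4L)))
  expect_identical(nrow(s8$table), 1L)
  expect_identical(nrow(s4$table), 3L)
})

test_that("segmentation is a pure function and respects the plate mask", {
  sim <- simulatePlate(quick_config(rng_seed = 5L))
  g <- plateGeometry(quick_config())
  f <- frames(sim$stack)[[12L]]
  a <- segmentFrame(f, 0.9, SegmentationParams(), g)
  b <- segmentFrame(f, 0.9, SegmentationParams(), g)
  expect_identical(a, b)
  rr <- sqrt((a$table$row - g@center_px[1L])^2 +
             (a$table$col - g@center_px[2L])^2)
  expect_true(all(rr <= g@plate_radius_px))
})

test_that("noise-free segmentation recovers exactly the visible objects", {
  cfg <- quick_config(n_viable = 6L, n_debris = 4L, rng_seed = 8L)
  sim <- simulatePlate(cfg)
  g <- plateGeometry(cfg)
  px <- pixelSize(sim$stack)
  for (f in c(1L, 8L, 12L, 16L)) {
    t_h <- frameTimes(sim$stack)[f]
    r_px <- colonyRadius(t_h, sim$truth$lag_h, sim$truth$rate_um_per_h,
                         sim$truth$r_max_um) / px
    visible <- sum(sim$truth$class == "debris" |
                   (sim$truth$class == "viable" & r_px >= 1))
    seg <- segmentFrame(frames(sim$stack)[[f]], 0.9, SegmentationParams(), g)
    expect_identical(nrow(seg$table), as.integer(visible))
  }
})
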