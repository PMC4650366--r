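test_that("linkDetections handles births, simple links and gates", {
  # no prior tracks: all detections start new tracks
  asg <- linkDetections(data.frame(row = numeric(), col = numeric()),
                        data.frame(row = c(1, 5, 9), col = c(1, 5, 9)), 5)
  expect_identical(asg, rep(NA_integer_, 3L))
  # within the gate: linked
  expect_identical(
    linkDetections(data.frame(row = 10, col = 10),
                   data.frame(row = 12, col = 10), 5), 1L)
  # outside the gate: new track
  expect_identical(
    linkDetections(data.frame(row = 10, col = 10),
                   data.frame(row = 30, col = 10), 5), NA_integer_)
})

test_that("greedy linking matches exhaustive assignment on small instances", {
  # crossed-distance pair from first principles
  tp <- cbind(c(0, 10), c(0, 0))
  dp <- cbind(c(1, 9), c(0, 0))
  expect_identical(
    linkDetections(data.frame(row = tp[, 1], col = tp[, 2]),
                   data.frame(row = dp[, 1], col = dp[, 2]), 5),
    exhaustive_assignment(tp, dp, 5))
  # randomized well-separated instances (static colonies + jitter): the
  # greedy result must equal the exhaustive minimal assignment
  set.seed(101)
  for (rep in 1:40) {
    nt <- sample(1:4, 1)
    base <- cbind(runif(nt, 0, 100), runif(nt, 0, 100))
    while (nt > 1 && min(dist(base)) < 15)
      base <- cbind(runif(nt, 0, 100), runif(nt, 0, 100))
    keep <- sort(sample(nt, sample(nt, 1)))
    dp <- base[keep, , drop = FALSE] +
      matrix(runif(2 * length(keep), -2, 2), ncol = 2)
    got <- linkDetections(data.frame(row = base[, 1], col = base[, 2]),
                          data.frame(row = dp[, 1], col = dp[, 2]), 5)
    expect_identical(got, exhaustive_assignment(base, dp, 5))
  }
})

test_that("detectFusion fires only when one component spans several tracks", {
  m <- function(px) {
    out <- matrix(FALSE, 10, 10)
    out[px] <- TRUE
    out
  }
  t1 <- m(cbind(3, 3)); t2 <- m(cbind(3, 7)); t3 <- m(cbind(7, 5))
  # two disjoint detections over two tracks: no event
  lab <- matrix(0L, 10, 10); lab[3, 3] <- 1L; lab[3, 7] <- 2L
  expect_length(detectFusion(lab, list(`1` = t1, `2` = t2)), 0L)
  # one component overlapping both masks: one event with both ids
  lab2 <- matrix(0L, 10, 10); lab2[3, 3:7] <- 1L
  ev <- detectFusion(lab2, list(`1` = t1, `2` = t2), frame_index = 6L)
  expect_length(ev, 1L)
  expect_setequal(ev[[1L]]$track_ids, c("1", "2"))
  expect_identical(ev[[1L]]$frame_index, 6L)
  # three-way fusion: one event, three ids
  lab3 <- matrix(0L, 10, 10); lab3[3:7, 3:7] <- 1L
  ev3 <- detectFusion(lab3, list(`1` = t1, `2` = t2, `3` = t3))
  expect_length(ev3, 1L)
  expect_setequal(ev3[[1L]]$track_ids, c("1", "2", "3"))
})

test_that("resolveDoublet counts merged pre-components, once", {
  m <- function(px) { out <- matrix(FALSE, 8, 8); out[px] <- TRUE; out }
  lab <- function(px, ids) {
    out <- matrix(0L, 8, 8); out[px] <- ids; out
  }
  # one blob in all frames: multiplicity 1
  single <- list(m(cbind(4, 4)), m(rbind(c(4, 4), c(4, 5))))
  labs1 <- list(lab(cbind(4, 4), 1L), lab(rbind(c(4, 4), c(4, 5)), 1L))
  expect_identical(resolveDoublet(single, labs1), 1L)
  # two 1-px blobs merging into one: multiplicity 2
  merged <- m(rbind(c(4, 4), c(4, 5), c(4, 6)))
  track_masks <- list(NULL, merged)
  labs2 <- list(lab(rbind(c(4, 4), c(4, 6)), c(1L, 2L)),
                lab(rbind(c(4, 4), c(4, 5), c(4, 6)), 1L))
  expect_identical(resolveDoublet(track_masks, labs2), 2L)
  # a fusion-tracked pair: the partner's component is excluded, so neither
  # track gains multiplicity (no double counting)
  expect_identical(resolveDoublet(track_masks, labs2,
                                  exclude = list(2L, NULL)), 1L)
})

test_that("classifyViability applies the growth rules", {
  p <- TrackingParams()   # growth_factor_min = 2, min_growth_frames = 2
  const <- data.frame(frame = 1:10, area_px = rep(4L, 10))
  expect_identical(classifyViability(const, p, last_frame = 10L), "static")
  grow <- data.frame(frame = 3:6, area_px = c(1L, 3L, 9L, 20L))
  expect_identical(classifyViability(grow, p, last_frame = 10L), "viable")
  late <- data.frame(frame = 9L, area_px = 2L)
  expect_identical(classifyViability(late, p, last_frame = 10L), "unresolved")
  expect_error(classifyViability(const[0, ], p, last_frame = 10L), "empty")
  # shrinking mid-stack object: neither viable nor present-from-0 static
  odd <- data.frame(frame = 4:7, area_px = c(5L, 4L, 3L, 2L))
  expect_identical(classifyViability(odd, p, last_frame = 10L), "unresolved")
})

test_that("count series counts viable tracks only, from their birth", {
  cfg <- quick_config(n_viable = 5L, n_debris = 3L, rng_seed = 21L)
  sim <- simulatePlate(cfg)
  tr <- trackColonies(sim$stack, geometry = plateGeometry(cfg))
  s <- countSeries(tr)
  expect_identical(counts(s)[length(s)], 5L)         # ground-truth oracle
  expect_true(all(diff(counts(s)) >= 0L))
  expect_identical(counts(s)[1L], 0L)                # debris contribute 0

  none <- trackColonies(simulatePlate(quick_config(n_viable = 0L,
                                                   n_debris = 4L,
                                                   rng_seed = 3L))$stack,
                        geometry = plateGeometry(cfg))
  expect_true(all(counts(countSeries(none)) == 0L))
})

test_that("fusion preserves the count through merges", {
  cfg <- quick_config(n_viable = 6L, n_debris = 0L, n_fusion_pairs = 2L,
                      r_max_um = 1200, growth_rate_um_per_h_mean = 80,
                      lag_mean_h = 4, lag_sd_h = 1, rng_seed = 11L)
  sim <- simulatePlate(cfg)
  tr <- trackColonies(sim$stack, geometry = plateGeometry(cfg))
  expect_gte(nrow(fusionEvents(tr)), 2L)
  s <- countSeries(tr)
  expect_true(all(diff(counts(s)) >= 0L))            # no drop at any merge
  expect_identical(counts(s)[length(s)], 6L)
  # fused tracks keep their identities and pre-fusion history
  ev <- fusionEvents(tr)
  ids <- as.integer(strsplit(ev$track_ids[1L], ",")[[1L]])
  expect_length(ids, 2L)
  for (id in ids) {
    h <- trackHistory(tr, id)
    expect_true(min(h$frame) < ev$frame[1L])         # history predates merge
    expect_true(max(h$frame) >= ev$frame[1L])
  }
})

test_that("noise-free recovery is exact; default noise stays within 1%", {
  cfg <- quick_config(n_viable = 40L, n_debris = 10L, sensor_px = 768L,
                      r_max_um = 500, rng_seed = 17L)
  sim <- simulatePlate(cfg)
  tr <- trackColonies(sim$stack, geometry = plateGeometry(cfg))
  expect_identical(sum(trackInfo(tr)$viability == "viable"), 40L)
  m <- matchTracksToTruth(tr, sim$truth)
  expect_identical(m$n_matched, 40L)

  cfgn <- quick_config(n_viable = 40L, n_debris = 10L, sensor_px = 768L,
                       r_max_um = 500, noise_sd = 0.02, rng_seed = 18L)
  simn <- simulatePlate(cfgn)
  trn <- trackColonies(simn$stack, geometry = plateGeometry(cfgn))
  n_v <- sum(trackInfo(trn)$viability == "viable")
  expect_lte(abs(n_v - 40L), ceiling(0.01 * 40))
})
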