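# Background intensity of rendered frames; shadows are subtracted from it,
# so noise can fluctuate both ways without clipping at the white point.
.BG <- 0.9

#' Colony radius under the linear-growth model
#'
#' A colony has zero radius before its lag time, then its radius grows
#' linearly at `rate_um_per_h` until it saturates at `r_max_um`. The model
#' is deliberately minimal: the dispersion of lag times alone produces the
#' rapid rise of the colony-count series to a steady level.
#'
#' @param t_h time since inoculation (h); vectorised.
#' @param lag_h lag before growth starts (h).
#' @param rate_um_per_h radial growth rate (um/h).
#' @param r_max_um maximum radius (um).
#' @return Radius in micrometres, non-decreasing in `t_h`.
#' @examples
#' colonyRadius(10, 5, 50, 2000)   # 250
#' @export
colonyRadius <- function(t_h, lag_h, rate_um_per_h, r_max_um) {
  if (any(c(t_h, lag_h, rate_um_per_h, r_max_um) < 0))
    stop("all arguments must be >= 0")
  pmin(pmax(t_h - lag_h, 0) * rate_um_per_h, r_max_um)
}

# truncated-normal draws (>= lower), by rejection
.rtnorm <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# current shadow sd (px) of each ground-truth object at time t_h; NA when the
# object casts no shadow (viable colony below the one-pixel threshold)
.sigma_px <- function(objects, t_h, px_um) {
  sig <- numeric(nrow(objects))
  for (i in seq_len(nrow(objects))) {
    if (objects$class[i] == "debris") {
      sig[i] <- objects$r_max_um[i] / px_um
    } else {
      r_px <- colonyRadius(t_h, objects$lag_h[i], objects$rate_um_per_h[i],
                           objects$r_max_um[i]) / px_um
      sig[i] <- if (r_px >= 1) r_px else NA_real_
    }
  }
  sig
}

#' Render one synthetic shadow frame
#'
#' Each object darkens the bright background by a Gaussian shadow profile
#' `shadow_depth * exp(-d^2 / (2 sigma^2))` with `sigma` equal to its current
#' radius in pixels (debris: its fixed particle size); overlapping shadows
#' add. A viable colony casts no shadow until its radius reaches one pixel,
#' the spatial precision of the system, so the frame at which a colony
#' appears is exactly the frame at which it crosses the recognition
#' threshold. Pixels outside the plate circle stay at the background level.
#'
#' @param objects ground-truth data.frame as produced by [simulatePlate()]
#'   (columns `class`, `x_px`, `y_px`, `lag_h`, `rate_um_per_h`, `r_max_um`).
#' @param t_h capture time (h).
#' @param config a [SimulationConfig-class].
#' @param plate_mask optional precomputed plate mask (logical matrix).
#' @param add_noise add Gaussian noise of sd `config@noise_sd` (consumes the
#'   R random stream).
#' @return Grayscale matrix in [0, 1].
#' @export
renderFrame <- function(objects, t_h, config, plate_mask = NULL,
                        add_noise = TRUE) {
  stopifnot(is(config, "SimulationConfig"))
  n_px <- config@sensor_px
  px_um <- pixelSizeUm(config@field_mm, config@sensor_px)
  geom <- plateGeometry(config)
  if (is.null(plate_mask)) plate_mask <- buildPlateMask(geom, c(n_px, n_px))
  depth <- matrix(0, n_px, n_px)
  if (nrow(objects)) {
    dd <- sqrt((objects$y_px - geom@center_px[1L])^2 +
               (objects$x_px - geom@center_px[2L])^2)
    if (any(dd > geom@plate_radius_px))
      stop("object center outside plate circle")
    sig <- .sigma_px(objects, t_h, px_um)
    for (i in seq_len(nrow(objects))) {
      s <- sig[i]
      if (is.na(s)) next
      w <- ceiling(3 * s)
      r0 <- max(1L, as.integer(round(objects$y_px[i])) - w)
      r1 <- min(n_px, as.integer(round(objects$y_px[i])) + w)
      c0 <- max(1L, as.integer(round(objects$x_px[i])) - w)
      c1 <- min(n_px, as.integer(round(objects$x_px[i])) + w)
      dr2 <- (r0:r1 - objects$y_px[i])^2
      dc2 <- (c0:c1 - objects$x_px[i])^2
      g <- config@shadow_depth * exp(-outer(dr2, dc2, "+") / (2 * s^2))
      g[g < 1e-4] <- 0
      depth[r0:r1, c0:c1] <- depth[r0:r1, c0:c1] + g
    }
  }
  depth[!plate_mask] <- 0
  img <- .BG - depth
  if (add_noise && config@noise_sd > 0)
    img <- img + matrix(stats::rnorm(n_px * n_px, 0, config@noise_sd),
                        n_px, n_px)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# Dart-throwing placement with pairwise exclusion. `r_excl` is the per-object
# exclusion radius (px); two objects must be at least
# 2.3 * (r_i + r_j) + 2 px apart so their Gaussian tails never sum above the
# segmentation depth threshold (non-fusion objects stay separate components).
.place <- function(n, r_excl, geom, rim = FALSE, existing = NULL,
                   max_tries_per_obj = 2000L) {
  R <- geom@plate_radius_px
  ctr <- geom@center_px
  pts <- matrix(NA_real_, n, 2L)  # (row, col)
  ex_pts <- existing$all_pts
  ex_r <- existing$all_r
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries_per_obj)) {
      if (rim) {
        rr <- sqrt(stats::runif(1, ((1 - geom@rim_fraction) * R / R)^2, 1)) * R
        rr <- min(rr, R - 1)
        rr <- max(rr, (1 - geom@rim_fraction) * R)
      } else {
        rmax_c <- max(1, (1 - geom@rim_fraction) * R - r_excl[i] - 1)
        rr <- sqrt(stats::runif(1)) * rmax_c
      }
      th <- stats::runif(1, 0, 2 * pi)
      p <- c(ctr[1L] + rr * sin(th), ctr[2L] + rr * cos(th))
      sep_ok <- TRUE
      if (!is.null(ex_pts) && nrow(ex_pts)) {
        d <- sqrt((ex_pts[, 1L] - p[1L])^2 + (ex_pts[, 2L] - p[2L])^2)
        sep_ok <- all(d >= 2.3 * (ex_r + r_excl[i]) + 2)
      }
      if (sep_ok) {
        pts[i, ] <- p
        ex_pts <- rbind(ex_pts, p)
        ex_r <- c(ex_r, r_excl[i])
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("plate too crowded: could not place object ", i, " of ", n,
           " within the placement-retry limit")
  }
  list(pts = pts, all_pts = ex_pts, all_r = ex_r)
}

#' Simulate a time-lapse plate with known ground truth
#'
#' Generates the study scenarios: viable colonies appearing after dispersed
#' lag times and growing to a capped radius; static debris particles (1-3 px)
#' visible from frame 0; optional colony pairs seeded close enough that their
#' shadows merge as they grow; and optional rim colonies whose lag is
#' extended by `delayed_extra_lag_h`, emulating retarded growth of cells
#' attached to the plate side wall. Identical configurations (including the
#' seed) give bit-identical stacks and ground truth.
#'
#' @param config a [SimulationConfig-class].
#' @return A list with `stack` (a [FrameStack-class]) and `truth`, a
#'   data.frame with one row per object: `object_id`, `class` (`viable` /
#'   `debris`), `x_px`/`y_px` (col/row centre), `lag_h`, `rate_um_per_h`,
#'   `r_max_um` (for debris: its particle size in um), `fusion_group`,
#'   `rim_flag`.
#' @examples
#' sim <- simulatePlate(SimulationConfig(sensor_px = 256L, n_viable = 4L,
#'                                       n_debris = 2L, n_frames = 8L,
#'                                       r_max_um = 1500, rng_seed = 1L))
#' sim$stack
#' @export
simulatePlate <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@rng_seed)
  px_um <- pixelSizeUm(config@field_mm, config@sensor_px)
  geom <- plateGeometry(config)
  r_max_px <- config@r_max_um / px_um
  n_pairfused <- 2L * config@n_fusion_pairs
  n_rim <- config@n_delayed_rim
  n_plain <- config@n_viable - n_pairfused - n_rim
  if (config@n_fusion_pairs > 0L && r_max_px < 2)
    stop("r_max_um too small for fusion pairs at this pixel size")

  placed <- list(pts = NULL, all_pts = NULL, all_r = NULL)
  truth <- data.frame()
  add_rows <- function(pts, class, fusion_group, rim_flag) {
    if (!nrow(pts)) return()
    truth <<- rbind(truth, data.frame(
      object_id = NA_integer_, class = class,
      x_px = pts[, 2L], y_px = pts[, 1L],
      lag_h = NA_real_, rate_um_per_h = NA_real_, r_max_um = NA_real_,
      fusion_group = fusion_group, rim_flag = rim_flag))
  }

  # fusion pairs: anchor placed with an enlarged exclusion radius, partner at
  # a fixed distance short of twice the merge radius so the pair fuses late
  if (config@n_fusion_pairs > 0L) {
    pair_sep <- max(5.6, 1.15 * r_max_px)
    anchors <- .place(config@n_fusion_pairs,
                      rep(r_max_px + pair_sep / 2, config@n_fusion_pairs),
                      geom, existing = placed)
    placed <- list(all_pts = anchors$all_pts, all_r = anchors$all_r)
    for (k in seq_len(config@n_fusion_pairs)) {
      th <- stats::runif(1, 0, 2 * pi)
      partner <- anchors$pts[k, ] + pair_sep * c(sin(th), cos(th))
      add_rows(rbind(anchors$pts[k, ], partner), "viable", k, FALSE)
    }
  }
  if (n_rim > 0L) {
    rimp <- .place(n_rim, rep(r_max_px, n_rim), geom, rim = TRUE,
                   existing = placed)
    placed <- list(all_pts = rimp$all_pts, all_r = rimp$all_r)
    add_rows(rimp$pts, "viable", NA_integer_, TRUE)
  }
  if (n_plain > 0L) {
    pp <- .place(n_plain, rep(r_max_px, n_plain), geom, existing = placed)
    placed <- list(all_pts = pp$all_pts, all_r = pp$all_r)
    add_rows(pp$pts, "viable", NA_integer_, FALSE)
  }
  debris_sigma_px <- if (config@n_debris > 0L)
    stats::runif(config@n_debris, 1, 3) else numeric()
  if (config@n_debris > 0L) {
    dp <- .place(config@n_debris, debris_sigma_px, geom, existing = placed)
    add_rows(dp$pts, "debris", NA_integer_, FALSE)
  }

  if (nrow(truth)) {
    truth$object_id <- seq_len(nrow(truth))
    vi <- truth$class == "viable"
    truth$lag_h[vi] <- .rtnorm(sum(vi), config@lag_mean_h, config@lag_sd_h)
    truth$lag_h[vi & truth$rim_flag] <-
      truth$lag_h[vi & truth$rim_flag] + config@delayed_extra_lag_h
    truth$rate_um_per_h[vi] <-
      .rtnorm(sum(vi), config@growth_rate_um_per_h_mean,
              config@growth_rate_um_per_h_sd,
              lower = 0.25 * config@growth_rate_um_per_h_mean)
    truth$r_max_um[vi] <- config@r_max_um
    truth$lag_h[!vi] <- 0
    truth$rate_um_per_h[!vi] <- 0
    truth$r_max_um[!vi] <- debris_sigma_px * px_um
  } else {
    truth <- data.frame(object_id = integer(), class = character(),
                        x_px = numeric(), y_px = numeric(), lag_h = numeric(),
                        rate_um_per_h = numeric(), r_max_um = numeric(),
                        fusion_group = integer(), rim_flag = logical())
  }
  rownames(truth) <- NULL

  times <- (seq_len(config@n_frames) - 1) * config@frame_interval_h
  mask <- buildPlateMask(geom, rep(config@sensor_px, 2L))
  frames <- lapply(times, function(t)
    renderFrame(truth, t, config, plate_mask = mask))
  list(stack = FrameStack(frames, times, px_um), truth = truth)
}
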