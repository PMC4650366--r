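#' @import methods
NULL

# ---------------------------------------------------------------------------
# Parameter classes
# ---------------------------------------------------------------------------

#' Simulation configuration for synthetic plate stacks
#'
#' Holds the geometry of the imaged plate, the frame schedule, and the
#' population parameters of the simulated objects: viable colonies (which
#' appear after a lag and grow), static debris particles (visible from the
#' first frame and never growing), colony pairs seeded close enough to fuse,
#' and delayed colonies in the plate rim band.
#'
#' Geometry defaults follow the standard setup: a 90 mm plate imaged on a
#' 1536 x 1536 sensor spanning 100 x 100 mm, so one pixel is ~65 um, the
#' spatial precision at which a colony is first recognised.
#'
#' @slot plate_diameter_mm plate diameter (mm).
#' @slot field_mm side length of the square imaged field (mm).
#' @slot sensor_px sensor side length in pixels.
#' @slot frame_interval_h time between frames (h).
#' @slot n_frames number of frames (>= 3).
#' @slot n_viable,n_debris numbers of viable colonies and debris particles.
#' @slot lag_mean_h,lag_sd_h lag-time distribution (truncated normal, h).
#' @slot growth_rate_um_per_h_mean,growth_rate_um_per_h_sd radial growth
#'   rate distribution (um/h, truncated at zero).
#' @slot r_max_um maximum colony radius (um).
#' @slot n_fusion_pairs number of viable colonies placed as close pairs that
#'   eventually merge (each pair uses two of `n_viable`).
#' @slot n_delayed_rim number of viable colonies placed in the rim band with
#'   `delayed_extra_lag_h` added to their lag.
#' @slot delayed_extra_lag_h extra lag of rim colonies (h).
#' @slot rim_fraction rim band width as a fraction of the plate radius.
#' @slot shadow_depth peak contrast of a colony shadow (0..1).
#' @slot noise_sd additive Gaussian pixel noise (image clipped to [0,1]).
#' @slot rng_seed integer seed; identical configs give bit-identical stacks.
#' @seealso [simulatePlate()]
#' @export
setClass("SimulationConfig",
  representation(
    plate_diameter_mm = "numeric", field_mm = "numeric",
    sensor_px = "integer", frame_interval_h = "numeric",
    n_frames = "integer", n_viable = "integer", n_debris = "integer",
    lag_mean_h = "numeric", lag_sd_h = "numeric",
    growth_rate_um_per_h_mean = "numeric", growth_rate_um_per_h_sd = "numeric",
    r_max_um = "numeric", n_fusion_pairs = "integer",
    n_delayed_rim = "integer", delayed_extra_lag_h = "numeric",
    rim_fraction = "numeric",
    shadow_depth = "numeric", noise_sd = "numeric", rng_seed = "integer"
  ),
  prototype(
    plate_diameter_mm = 90, field_mm = 100, sensor_px = 1536L,
    frame_interval_h = 1, n_frames = 16L, n_viable = 50L, n_debris = 10L,
    lag_mean_h = 6, lag_sd_h = 2,
    growth_rate_um_per_h_mean = 40, growth_rate_um_per_h_sd = 8,
    r_max_um = 400, n_fusion_pairs = 0L, n_delayed_rim = 0L,
    delayed_extra_lag_h = 8, rim_fraction = 0.05,
    shadow_depth = 0.6, noise_sd = 0.02, rng_seed = 1L
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@sensor_px <= 0L) msg <- c(msg, "sensor_px must be > 0")
  if (object@plate_diameter_mm > object@field_mm)
    msg <- c(msg, "plate_diameter_mm must not exceed field_mm")
  if (object@n_frames < 3L) msg <- c(msg, "n_frames must be >= 3")
  counts <- c(object@n_viable, object@n_debris, object@n_fusion_pairs,
              object@n_delayed_rim)
  if (any(counts < 0L)) msg <- c(msg, "object counts must be >= 0")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@shadow_depth < 0 || object@shadow_depth > 1)
    msg <- c(msg, "shadow_depth must be in [0, 1]")
  if (object@rim_fraction <= 0 || object@rim_fraction >= 1)
    msg <- c(msg, "rim_fraction must be in (0, 1)")
  if (2L * object@n_fusion_pairs + object@n_delayed_rim > object@n_viable)
    msg <- c(msg, "fusion pairs and delayed rim colonies exceed n_viable")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param ... named slots overriding the defaults; see
#'   [SimulationConfig-class] for the full list.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(n_viable = 5L, n_debris = 3L, rng_seed = 7L)
#' @export
SimulationConfig <- function(...) {
  args <- list(...)
  int_slots <- c("sensor_px", "n_frames", "n_viable", "n_debris",
                 "n_fusion_pairs", "n_delayed_rim", "rng_seed")
  for (s in names(args))
    args[[s]] <- if (s %in% int_slots) as.integer(args[[s]])
                 else as.numeric(args[[s]])
  do.call(new, c(list("SimulationConfig"), args))
}

#' Segmentation parameters
#'
#' @slot depth_threshold contrast below the background level at which a pixel
#'   is called foreground (0..1).
#' @slot min_area_px minimum component area in pixels; the default 1 encodes
#'   the one-pixel (~65 um) colony recognition threshold.
#' @slot connectivity 4 or 8 (default 8, so diagonally touching shadow pixels
#'   are not split).
#' @export
setClass("SegmentationParams",
  representation(depth_threshold = "numeric", min_area_px = "integer",
                 connectivity = "integer"),
  prototype(depth_threshold = 0.1, min_area_px = 1L, connectivity = 8L)
)

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@depth_threshold <= 0 || object@depth_threshold >= 1)
    msg <- c(msg, "depth_threshold must be in (0, 1)")
  if (object@min_area_px < 1L) msg <- c(msg, "min_area_px must be >= 1")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (length(msg)) msg else TRUE
})

#' @rdname SegmentationParams-class
#' @param ... named slots overriding the defaults.
#' @export
SegmentationParams <- function(...) {
  args <- list(...)
  for (s in intersect(names(args), c("min_area_px", "connectivity")))
    args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("SegmentationParams"), args))
}

#' Tracking parameters
#'
#' @slot max_link_px linking gate: a detection may continue a track only if
#'   its centroid is within this distance (px) of the track's last centroid.
#'   Colonies do not move, so the gate is tight.
#' @slot growth_factor_min a track is growing once its area reaches this
#'   multiple of its birth area (> 1).
#' @slot min_growth_frames minimum length (frames) of a non-decreasing area
#'   run required to call a track viable.
#' @slot confirm_frames tracks born within this many frames of the end of the
#'   stack cannot yet be classified and stay `unresolved`.
#' @slot grace_frames frames a track survives without a detection before it
#'   is ended.
#' @export
setClass("TrackingParams",
  representation(max_link_px = "numeric", growth_factor_min = "numeric",
                 min_growth_frames = "integer", confirm_frames = "integer",
                 grace_frames = "integer"),
  prototype(max_link_px = 5, growth_factor_min = 2, min_growth_frames = 2L,
            confirm_frames = 2L, grace_frames = 1L)
)

setValidity("TrackingParams", function(object) {
  msg <- character()
  if (object@max_link_px <= 0) msg <- c(msg, "max_link_px must be > 0")
  if (object@growth_factor_min <= 1)
    msg <- c(msg, "growth_factor_min must be > 1")
  if (object@min_growth_frames < 1L)
    msg <- c(msg, "min_growth_frames must be >= 1")
  if (object@confirm_frames < 0L) msg <- c(msg, "confirm_frames must be >= 0")
  if (object@grace_frames < 0L) msg <- c(msg, "grace_frames must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname TrackingParams-class
#' @param ... named slots overriding the defaults.
#' @export
TrackingParams <- function(...) {
  args <- list(...)
  for (s in intersect(names(args),
                      c("min_growth_frames", "confirm_frames", "grace_frames")))
    args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("TrackingParams"), args))
}

#' Plate geometry in sensor coordinates
#'
#' Pixel coordinates are 1-based (row, col) matrix indices; centroids are
#' means of member pixel indices.
#'
#' @slot center_px numeric length-2, (row, col) of the plate centre.
#' @slot plate_radius_px plate radius in pixels.
#' @slot rim_fraction the rim band is the annulus of radii in
#'   `[(1 - rim_fraction) * R, R]`.
#' @export
setClass("PlateGeometry",
  representation(center_px = "numeric", plate_radius_px = "numeric",
                 rim_fraction = "numeric"),
  prototype(center_px = c(768.5, 768.5), plate_radius_px = 691.2,
            rim_fraction = 0.05)
)

setValidity("PlateGeometry", function(object) {
  msg <- character()
  if (length(object@center_px) != 2L)
    msg <- c(msg, "center_px must have length 2")
  if (object@plate_radius_px < 0) msg <- c(msg, "plate_radius_px must be >= 0")
  if (object@rim_fraction <= 0 || object@rim_fraction >= 1)
    msg <- c(msg, "rim_fraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname PlateGeometry-class
#' @param center_px (row, col) plate centre in pixels.
#' @param plate_radius_px plate radius in pixels.
#' @param rim_fraction rim band width as a fraction of the radius.
#' @export
PlateGeometry <- function(center_px, plate_radius_px, rim_fraction = 0.05) {
  new("PlateGeometry", center_px = as.numeric(center_px),
      plate_radius_px = as.numeric(plate_radius_px),
      rim_fraction = rim_fraction)
}

#' Derive the plate geometry implied by a simulation configuration
#'
#' @param config a [SimulationConfig-class] (its sensor size, field of view
#'   and plate diameter fix the plate circle on the sensor).
#' @return A [PlateGeometry-class] centred on the sensor.
#' @export
plateGeometry <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  px_um <- pixelSizeUm(config@field_mm, config@sensor_px)
  ctr <- (config@sensor_px + 1) / 2
  PlateGeometry(center_px = c(ctr, ctr),
                plate_radius_px = config@plate_diameter_mm * 500 / px_um,
                rim_fraction = config@rim_fraction)
}

# ---------------------------------------------------------------------------
# Data classes
# ---------------------------------------------------------------------------

#' Time-lapse frame stack of one plate
#'
#' An ordered set of grayscale frames (matrices with values in [0, 1];
#' background bright, colony shadows dark) with their capture times and the
#' physical pixel size.
#'
#' @slot frames list of numeric matrices, all the same dimension.
#' @slot times_h strictly increasing capture times (h).
#' @slot pixel_size_um physical side of one pixel (um).
#' @seealso [simulatePlate()], [readFrameStack()], [writeFrameStack()]
#' @export
setClass("FrameStack",
  representation(frames = "list", times_h = "numeric",
                 pixel_size_um = "numeric")
)

setValidity("FrameStack", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@times_h))
    msg <- c(msg, "frames and times_h must have the same length")
  if (length(object@times_h) > 1L && any(diff(object@times_h) <= 0))
    msg <- c(msg, "times_h must be strictly increasing")
  if (length(object@frames)) {
    d <- dim(object@frames[[1L]])
    ok <- vapply(object@frames,
                 function(f) is.matrix(f) && identical(dim(f), d), logical(1))
    if (!all(ok)) msg <- c(msg, "all frames must be matrices of equal dim")
  }
  if (length(object@pixel_size_um) != 1L || object@pixel_size_um <= 0)
    msg <- c(msg, "pixel_size_um must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' @rdname FrameStack-class
#' @param frames list of grayscale matrices.
#' @param times_h capture times (h).
#' @param pixel_size_um pixel size (um).
#' @export
FrameStack <- function(frames, times_h, pixel_size_um) {
  new("FrameStack", frames = frames, times_h = as.numeric(times_h),
      pixel_size_um = as.numeric(pixel_size_um))
}

#' Tracked colonies of one plate
#'
#' The result of [trackColonies()]: one row of `info` per track, with its
#' full per-frame history, plus the fusion events in which growing colonies
#' merged into a single connected shadow (fused tracks keep their identity
#' and keep being counted individually).
#'
#' @slot info data.frame with one row per track: `track_id`, `birth_frame`,
#'   `last_frame`, `status` (`active`, `fused`, `ended`), `viability`
#'   (`viable`, `static`, `unresolved`), `fusion_group` (NA or integer),
#'   `multiplicity` (>= 1, doublet colonies resolved from temporal
#'   evidence), `rim_flag`.
#' @slot history list (parallel to `info`) of data.frames with columns
#'   `frame`, `area_px`, `row`, `col`, `mean_depth`, `label`.
#' @slot fusions data.frame of fusion events: `frame`, `fusion_group`,
#'   `component_label`, `track_ids` (comma-separated).
#' @slot times_h frame capture times (h).
#' @export
setClass("ColonyTrackSet",
  representation(info = "data.frame", history = "list", fusions = "data.frame",
                 times_h = "numeric")
)

setValidity("ColonyTrackSet", function(object) {
  msg <- character()
  need <- c("track_id", "birth_frame", "last_frame", "status", "viability",
            "fusion_group", "multiplicity", "rim_flag")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@info) != length(object@history))
    msg <- c(msg, "one history entry per track required")
  if (nrow(object@info) && any(object@info$multiplicity < 1L))
    msg <- c(msg, "multiplicity must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Colony-count time series of one plate
#'
#' The number of registered viable colonies N_i at each capture time i
#' (0-based frame index i in the notation; stored 1-based in R).
#'
#' @slot times_h strictly increasing capture times (h).
#' @slot counts integer counts N_i, same length as `times_h`.
#' @seealso [countSeries()], [findSteady()], [confirmCount()]
#' @export
setClass("CountSeries",
  representation(times_h = "numeric", counts = "integer")
)

setValidity("CountSeries", function(object) {
  msg <- character()
  if (length(object@times_h) != length(object@counts))
    msg <- c(msg, "times_h and counts must have the same length")
  if (length(object@times_h) > 1L && any(diff(object@times_h) <= 0))
    msg <- c(msg, "times_h must be strictly increasing")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname CountSeries-class
#' @param times_h capture times (h).
#' @param counts integer colony counts.
#' @export
CountSeries <- function(times_h, counts) {
  new("CountSeries", times_h = as.numeric(times_h),
      counts = as.integer(round(counts)))
}

#' Steady-level decision on a count series
#'
#' Produced by [findSteady()]. When a qualifying window (i, i+1, i+2) is
#' found, `n_stdy = counts[i+2]` and `t_stdy_h = times[i+2]` (window indices
#' here are 1-based R indices into the series).
#'
#' @slot found whether any window qualified.
#' @slot window_start_i 1-based index of the first qualifying window start
#'   (NA if not found).
#' @slot n_stdy steady-level count (NA if not found).
#' @slot t_stdy_h time at which the steady level is declared (NA if not
#'   found).
#' @slot criterion_used `"large_n"` (relative 1\% rule, N_i > 100) or
#'   `"small_n"` (absolute +/-1 rule, N_i <= 100).
#' @export
setClass("SteadyDecision",
  representation(found = "logical", window_start_i = "integer",
                 n_stdy = "integer", t_stdy_h = "numeric",
                 criterion_used = "character")
)

#' Cross-plate equivalence statistics
#'
#' Ordinary least squares of log10(N_conf) on log10(N_stdy) across plates,
#' the Pearson correlation with its significance, and a paired t-test on the
#' determination times.
#'
#' @slot n_pairs number of plates.
#' @slot slope,intercept coefficients of
#'   `log10(N_conf) = slope * log10(N_stdy) + intercept`.
#' @slot r,r_squared Pearson correlation of the log counts and its square.
#' @slot df degrees of freedom used for the correlation test (per the
#'   configured convention).
#' @slot p_corr two-sided p-value of the correlation.
#' @slot t_stat_times,df_times,p_times paired two-sided t-test of
#'   `t_conf - t_stdy`.
#' @slot df_convention `"n_minus_2"` or `"n_minus_1"`.
#' @export
setClass("EquivalenceStats",
  representation(n_pairs = "integer", slope = "numeric", intercept = "numeric",
                 r = "numeric", r_squared = "numeric", df = "integer",
                 p_corr = "numeric", t_stat_times = "numeric",
                 df_times = "integer", p_times = "numeric",
                 df_convention = "character")
)
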