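#' @rdname FrameStack-class
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)

#' @rdname FrameStack-class
#' @export
setMethod("frameTimes", "FrameStack", function(x) x@times_h)

#' @rdname FrameStack-class
#' @export
setMethod("pixelSize", "FrameStack", function(x) x@pixel_size_um)

#' @rdname FrameStack-class
#' @export
setMethod("nFrames", "FrameStack", function(x) length(x@frames))

#' @rdname FrameStack-class
#' @param i frame index.
#' @export
setMethod("[[", "FrameStack", function(x, i) x@frames[[i]])

#' @rdname FrameStack-class
#' @export
setMethod("length", "FrameStack", function(x) length(x@frames))

setMethod("show", "FrameStack", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1L]]) else c(0L, 0L)
  cat(sprintf("FrameStack: %d frames of %d x %d px (%.1f um/px)\n",
              length(object@frames), d[1L], d[2L], object@pixel_size_um))
  if (length(object@times_h))
    cat(sprintf("  times: %.2g .. %.4g h\n",
                object@times_h[1L], object@times_h[length(object@times_h)]))
})

#' @rdname ColonyTrackSet-class
#' @export
setMethod("trackInfo", "ColonyTrackSet", function(x) x@info)

#' @rdname ColonyTrackSet-class
#' @export
setMethod("trackHistory", "ColonyTrackSet", function(x, id) {
  j <- match(id, x@info$track_id)
  if (is.na(j)) stop("unknown track_id: ", id)
  x@history[[j]]
})

#' @rdname ColonyTrackSet-class
#' @export
setMethod("fusionEvents", "ColonyTrackSet", function(x) x@fusions)

#' @rdname ColonyTrackSet-class
#' @export
setMethod("frameTimes", "ColonyTrackSet", function(x) x@times_h)

setMethod("show", "ColonyTrackSet", function(object) {
  tab <- table(factor(object@info$viability,
                      levels = c("viable", "static", "unresolved")))
  cat(sprintf(paste0("ColonyTrackSet: %d tracks over %d frames ",
                     "(%d viable, %d static, %d unresolved), %d fusion event(s)\n"),
              nrow(object@info), length(object@times_h),
              tab[["viable"]], tab[["static"]], tab[["unresolved"]],
              nrow(object@fusions)))
})

#' @rdname CountSeries-class
#' @export
setMethod("counts", "CountSeries", function(x) x@counts)

#' @rdname CountSeries-class
#' @export
setMethod("frameTimes", "CountSeries", function(x) x@times_h)

#' @rdname CountSeries-class
#' @export
setMethod("length", "CountSeries", function(x) length(x@counts))

setMethod("show", "CountSeries", function(object) {
  n <- length(object@counts)
  cat(sprintf("CountSeries: %d time points", n))
  if (n) cat(sprintf(", final N = %d at %.4g h",
                     object@counts[n], object@times_h[n]))
  cat("\n")
})

#' @rdname SteadyDecision-class
#' @export
setMethod("steadyFound", "SteadyDecision", function(x) x@found)

#' @rdname SteadyDecision-class
#' @export
setMethod("nStdy", "SteadyDecision", function(x) x@n_stdy)

#' @rdname SteadyDecision-class
#' @export
setMethod("tStdy", "SteadyDecision", function(x) x@t_stdy_h)

#' @rdname SteadyDecision-class
#' @export
setMethod("criterionUsed", "SteadyDecision", function(x) x@criterion_used)

setMethod("show", "SteadyDecision", function(object) {
  if (object@found)
    cat(sprintf("SteadyDecision: N_stdy = %d at %.4g h (window %d, %s criterion)\n",
                object@n_stdy, object@t_stdy_h, object@window_start_i,
                object@criterion_used))
  else cat("SteadyDecision: no steady level reached\n")
})

setMethod("show", "EquivalenceStats", function(object) {
  cat(sprintf("EquivalenceStats over %d plates:\n", object@n_pairs))
  cat(sprintf("  log10(N_conf) = %.4f * log10(N_stdy) %+.4f\n",
              object@slope, object@intercept))
  cat(sprintf("  r = %.4f (R^2 = %.4f), df = %d, p = %.3g\n",
              object@r, object@r_squared, object@df, object@p_corr))
  cat(sprintf("  paired t-test on times: t = %.3f, df = %d, p = %.3g\n",
              object@t_stat_times, object@df_times, object@p_times))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %g mm plate on %d px sensor ",
                     "(%g mm field), %d frames every %g h\n"),
              object@plate_diameter_mm, object@sensor_px, object@field_mm,
              object@n_frames, object@frame_interval_h))
  cat(sprintf("  %d viable (%d fusion pairs, %d delayed rim), %d debris, seed %d\n",
              object@n_viable, object@n_fusion_pairs, object@n_delayed_rim,
              object@n_debris, object@rng_seed))
})
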