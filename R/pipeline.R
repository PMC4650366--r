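#' Match viable tracks to simulator ground truth
#'
#' Greedy one-to-one matching (ascending distance) between the birth
#' centroids of viable tracks and the seeded positions of viable
#' ground-truth objects, within a distance gate. Used to validate the
#' pipeline on simulated plates.
#'
#' @param tracks a [ColonyTrackSet-class].
#' @param truth ground-truth data.frame from [simulatePlate()].
#' @param max_dist_px matching gate (px).
#' @return A list with `n_truth_viable`, `n_tracks_viable`, `n_matched`,
#'   and `matches` (data.frame `object_id`, `track_id`, `dist_px`).
#' @export
matchTracksToTruth <- function(tracks, truth, max_dist_px = 5) {
  stopifnot(is(tracks, "ColonyTrackSet"))
  info <- tracks@info
  vi <- which(info$viability == "viable")
  tv <- truth[truth$class == "viable", , drop = FALSE]
  if (!length(vi) || !nrow(tv))
    return(list(n_truth_viable = nrow(tv), n_tracks_viable = length(vi),
                n_matched = 0L,
                matches = data.frame(object_id = integer(),
                                     track_id = integer(),
                                     dist_px = numeric())))
  pos <- t(vapply(vi, function(j) {
    h <- tracks@history[[j]]
    c(h$row[1L], h$col[1L])
  }, numeric(2)))
  d2 <- outer(tv$y_px, pos[, 1L], "-")^2 + outer(tv$x_px, pos[, 2L], "-")^2
  cand <- which(d2 <= max_dist_px^2)
  cand <- cand[order(d2[cand])]
  no <- nrow(tv)
  o_used <- logical(no); t_used <- logical(length(vi))
  matches <- list()
  for (k in cand) {
    oi <- ((k - 1L) %% no) + 1L
    ti <- ((k - 1L) %/% no) + 1L
    if (!o_used[oi] && !t_used[ti]) {
      o_used[oi] <- TRUE; t_used[ti] <- TRUE
      matches[[length(matches) + 1L]] <-
        data.frame(object_id = tv$object_id[oi],
                   track_id = info$track_id[vi[ti]],
                   dist_px = sqrt(d2[k]))
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(object_id = integer(), track_id = integer(),
               dist_px = numeric())
  list(n_truth_viable = nrow(tv), n_tracks_viable = length(vi),
       n_matched = nrow(matches), matches = matches)
}

#' Simulate a plate and write its stack, ground truth and config
#'
#' Writes `stack.tif` (multi-page 16-bit), `times.csv`, `truth.csv` and
#' `config.json` into `out_dir`. The simulation runs before anything is
#' written, so a failed (e.g. over-crowded) configuration leaves no partial
#' output.
#'
#' @param config a [SimulationConfig-class].
#' @param out_dir output directory (created if needed).
#' @return The simulation result of [simulatePlate()], invisibly.
#' @export
runSimulate <- function(config, out_dir) {
  sim <- simulatePlate(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeFrameStack(sim$stack, file.path(out_dir, "stack.tif"),
                  times_path = file.path(out_dir, "times.csv"))
  writeGroundTruth(sim$truth, file.path(out_dir, "truth.csv"))
  writeConfig(config, file.path(out_dir, "config.json"))
  invisible(sim)
}

# red registered-colony markers on a grayscale frame
.overlay_png <- function(frame, centers, path, radius = 4L) {
  nr <- nrow(frame); nc <- ncol(frame)
  rgb <- array(frame, dim = c(nr, nc, 3L))
  if (nrow(centers)) {
    th <- seq(0, 2 * pi, length.out = 24L)
    for (k in seq_len(nrow(centers))) {
      rr <- pmin(pmax(round(centers$row[k] + radius * sin(th)), 1L), nr)
      cc <- pmin(pmax(round(centers$col[k] + radius * cos(th)), 1L), nc)
      ii <- cbind(rr, cc)
      rgb[cbind(ii, 1L)] <- 1
      rgb[cbind(ii, 2L)] <- 0
      rgb[cbind(ii, 3L)] <- 0
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Analyze one plate stack end to end
#'
#' Runs segmentation, tracking, counting, the steady-level decision and the
#' outcome classification on a frame stack, optionally writing the
#' count-series CSV, a per-plate JSON report, per-frame overlay PNGs with
#' registered-colony markers, and the per-colony image store.
#'
#' @param input a [FrameStack-class], or a path to a multi-page TIFF or a
#'   frame directory (see [readFrameStack()]).
#' @param out_dir optional output directory for `counts.csv` and
#'   `report.json` (and overlays under `overlays/`).
#' @param seg_params a [SegmentationParams-class].
#' @param track_params a [TrackingParams-class].
#' @param geometry optional [PlateGeometry-class].
#' @param times_csv,interval_h frame times when `input` is a path.
#' @param overlays write overlay PNGs (only when `out_dir` is given).
#' @param store_root when given, record every colony's crop series there
#'   via [recordPlate()].
#' @param plate_id plate identifier used in the report and the store.
#' @return A list with `report` (named list as written to JSON), `tracks`,
#'   `series`, `decision`, `confirmed` and `outcome`.
#' @export
runAnalyze <- function(input, out_dir = NULL,
                       seg_params = SegmentationParams(),
                       track_params = TrackingParams(), geometry = NULL,
                       times_csv = NULL, interval_h = 1, overlays = FALSE,
                       store_root = NULL, plate_id = "plate") {
  stack <- if (is(input, "FrameStack")) input
           else readFrameStack(input, times_csv = times_csv,
                               interval_h = interval_h)
  if (length(stack@frames) < 3L)
    stop("at least 3 frames are required for a steady-level decision")
  tracks <- trackColonies(stack, seg_params, track_params, geometry)
  series <- countSeries(tracks)
  decision <- findSteady(series)
  confirmed <- confirmCount(series)
  outcome <- classifyOutcome(series, decision, confirmed, tracks)
  rel <- if (decision@found && confirmed$n_conf > 0)
    relativeDifference(decision@n_stdy, confirmed$n_conf) else NA_real_
  report <- list(
    plate_id = plate_id,
    n_frames = length(stack@frames),
    n_tracks = nrow(tracks@info),
    n_viable_tracks = sum(tracks@info$viability == "viable"),
    n_fusion_events = nrow(tracks@fusions),
    n_stdy = decision@n_stdy, t_stdy_h = decision@t_stdy_h,
    criterion_used = decision@criterion_used,
    n_conf = confirmed$n_conf, t_conf_h = confirmed$t_conf_h,
    relative_difference_pct = rel,
    scenario = outcome$scenario,
    late_track_ids = outcome$late_track_ids,
    params = list(
      depth_threshold = seg_params@depth_threshold,
      min_area_px = seg_params@min_area_px,
      connectivity = seg_params@connectivity,
      max_link_px = track_params@max_link_px,
      growth_factor_min = track_params@growth_factor_min,
      min_growth_frames = track_params@min_growth_frames,
      confirm_frames = track_params@confirm_frames))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeCountSeries(series, file.path(out_dir, "counts.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    if (overlays) {
      od <- file.path(out_dir, "overlays")
      dir.create(od, showWarnings = FALSE)
      info <- tracks@info
      vi <- which(info$viability == "viable")
      for (f in seq_along(stack@frames)) {
        vis <- vi[info$birth_frame[vi] <= f]
        centers <- do.call(rbind, lapply(vis, function(j) {
          h <- tracks@history[[j]]
          k <- max(which(h$frame <= f))
          data.frame(row = h$row[k], col = h$col[k])
        }))
        if (is.null(centers))
          centers <- data.frame(row = numeric(), col = numeric())
        .overlay_png(stack@frames[[f]], centers,
                     file.path(od, sprintf("frame_%03d.png", f)))
      }
    }
  }
  if (!is.null(store_root))
    recordPlate(plate_id, stack, tracks, root = store_root)
  list(report = report, tracks = tracks, series = series,
       decision = decision, confirmed = confirmed, outcome = outcome)
}

#' Analyze a batch of plates and compute equivalence statistics
#'
#' Processes the plates sequentially, aggregates the per-plate reports, and
#' — when at least three plates reached a steady level — fits the log-log
#' regression of confirmed on rapid counts and the paired t-test on
#' determination times across plates. A failing plate is logged and
#' skipped; the batch fails only if every plate fails.
#'
#' @param inputs list of inputs accepted by [runAnalyze()] (paths or
#'   [FrameStack-class] objects), optionally named with plate ids.
#' @param out_dir optional directory for `equivalence.csv` and
#'   `equivalence.json`.
#' @param df_convention see [loglogRegression()].
#' @param ... further arguments passed to [runAnalyze()].
#' @return A list with `reports` (per plate), `pairs` (data.frame of
#'   `plate_id`, `n_stdy`, `t_stdy_h`, `n_conf`, `t_conf_h`) and `stats`
#'   (an [EquivalenceStats-class], or `NULL` when fewer than 3 plates have
#'   a steady level).
#' @export
runBatch <- function(inputs, out_dir = NULL,
                     df_convention = c("n_minus_2", "n_minus_1"), ...) {
  df_convention <- match.arg(df_convention)
  ids <- names(inputs)
  if (is.null(ids)) ids <- sprintf("plate%03d", seq_along(inputs))
  reports <- list(); rows <- list()
  n_fail <- 0L
  for (k in seq_along(inputs)) {
    res <- tryCatch(runAnalyze(inputs[[k]], plate_id = ids[k], ...),
                    error = function(e) {
                      warning("plate ", ids[k], " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    reports[[ids[k]]] <- res$report
    if (res$decision@found)
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = ids[k], n_stdy = res$decision@n_stdy,
        t_stdy_h = res$decision@t_stdy_h, n_conf = res$confirmed$n_conf,
        t_conf_h = res$confirmed$t_conf_h)
  }
  if (n_fail == length(inputs)) stop("all plates failed")
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plate_id = character(), n_stdy = integer(),
               t_stdy_h = numeric(), n_conf = integer(), t_conf_h = numeric())
  stats <- NULL
  if (nrow(pairs) >= 3L) {
    stats <- equivalenceStats(pairs$n_stdy, pairs$n_conf, pairs$t_stdy_h,
                              pairs$t_conf_h, df_convention)
  } else {
    warning("fewer than 3 plates with a steady level; ",
            "equivalence statistics skipped")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pairs, file.path(out_dir, "equivalence.csv"),
                     row.names = FALSE)
    out <- list(n_plates = length(inputs), n_failed = n_fail,
                pairs = pairs)
    if (!is.null(stats))
      out$stats <- list(slope = stats@slope, intercept = stats@intercept,
                        r = stats@r, r_squared = stats@r_squared,
                        df = stats@df, p_corr = stats@p_corr,
                        t_stat_times = stats@t_stat_times,
                        df_times = stats@df_times, p_times = stats@p_times,
                        df_convention = stats@df_convention)
    jsonlite::write_json(out, file.path(out_dir, "equivalence.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  list(reports = reports, pairs = pairs, stats = stats)
}
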