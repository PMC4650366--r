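#' Greedy nearest-neighbour linking of detections to tracks
#'
#' Candidate (track, detection) pairs within `max_link_px` are assigned
#' greedily by ascending centroid distance, one detection per track and one
#' track per detection. Colonies do not move, so the default gate is tight.
#'
#' @param track_pos data.frame/matrix with columns `row`, `col`: last
#'   centroids of the active tracks.
#' @param det_pos data.frame/matrix with columns `row`, `col`: detection
#'   centroids of the new frame.
#' @param max_link_px linking gate (px).
#' @return Integer vector with one element per detection: the row index of
#'   the track it continues, or `NA` for detections that start new tracks.
#' @export
linkDetections <- function(track_pos, det_pos, max_link_px = 5) {
  track_pos <- as.matrix(as.data.frame(track_pos)[, c("row", "col")])
  det_pos <- as.matrix(as.data.frame(det_pos)[, c("row", "col")])
  nt <- nrow(track_pos); nd <- nrow(det_pos)
  out <- rep(NA_integer_, nd)
  if (!nt || !nd) return(out)
  d2 <- outer(track_pos[, 1L], det_pos[, 1L], "-")^2 +
        outer(track_pos[, 2L], det_pos[, 2L], "-")^2
  cand <- which(d2 <= max_link_px^2)
  if (!length(cand)) return(out)
  cand <- cand[order(d2[cand])]
  t_used <- logical(nt); d_used <- logical(nd)
  for (k in cand) {
    ti <- ((k - 1L) %% nt) + 1L
    di <- ((k - 1L) %/% nt) + 1L
    if (!t_used[ti] && !d_used[di]) {
      out[di] <- ti
      t_used[ti] <- TRUE
      d_used[di] <- TRUE
    }
  }
  out
}

#' Detect colony fusion events in one frame
#'
#' A fusion is a single connected component of the new frame whose mask
#' overlaps the last masks of two or more active tracks: the colonies have
#' grown into one shadow. The involved tracks keep their identities and keep
#' being counted individually, so no count is lost to fusion.
#'
#' @param det_labels integer label matrix of the new frame's components.
#' @param track_masks named list of logical matrices: each active track's
#'   most recent mask (names are track ids).
#' @param frame_index frame index recorded in the events.
#' @return A list of fusion events, each a list with `frame_index`,
#'   `component_label` and `track_ids` (>= 2 ids).
#' @export
detectFusion <- function(det_labels, track_masks, frame_index = NA_integer_) {
  if (!length(track_masks)) return(list())
  labs <- sort(unique(det_labels[det_labels > 0L]))
  events <- list()
  for (L in labs) {
    comp <- det_labels == L
    hit <- vapply(track_masks, function(m) any(m & comp), logical(1))
    if (sum(hit) >= 2L)
      events[[length(events) + 1L]] <-
        list(frame_index = frame_index, component_label = L,
             track_ids = names(track_masks)[hit])
  }
  events
}

#' Resolve doublet multiplicity from temporal evidence
#'
#' A doublet colony (one apparent colony that originated from two cells) is
#' recognised purely from the time lapse: in some earlier frame its region
#' was two (or more) distinct components that later merged into the track's
#' single mask. The multiplicity is the maximum, over the track's frames, of
#' the number of distinct previous-frame components contained in the track's
#' mask; components that belong to other tracks are excluded so that a
#' fusion-tracked pair (already two tracks) is not double counted. A track
#' that is a single component from birth has multiplicity 1. No single-frame
#' shape analysis is used.
#'
#' @param track_masks list over frames (entries `NULL` where the track is
#'   absent) of logical matrices: the track's own mask.
#' @param component_labels list over frames of integer label matrices of all
#'   segmented components.
#' @param exclude optional list over frames of integer vectors: component
#'   labels owned by other tracks.
#' @return Integer multiplicity >= 1.
#' @export
resolveDoublet <- function(track_masks, component_labels, exclude = NULL) {
  n <- length(track_masks)
  mult <- 1L
  for (f in seq_len(n)[-1L]) {
    if (is.null(track_masks[[f]]) || is.null(component_labels[[f - 1L]])) next
    prev_labs <- unique(component_labels[[f - 1L]][track_masks[[f]]])
    prev_labs <- prev_labs[prev_labs > 0L]
    if (!is.null(exclude) && !is.null(exclude[[f - 1L]]))
      prev_labs <- setdiff(prev_labs, exclude[[f - 1L]])
    mult <- max(mult, length(prev_labs))
  }
  as.integer(mult)
}

#' Classify a track as viable colony, static particle, or unresolved
#'
#' Growth is the evidence of viability: a track is `viable` once its area
#' reaches `growth_factor_min` times its birth area and it shows a run of at
#' least `min_growth_frames` frames of non-decreasing area. A track present
#' from the first frame whose area never changes by that factor is a
#' `static` particle (debris). Tracks born within `confirm_frames` of the
#' end of the stack — or otherwise lacking the evidence for either call —
#' are `unresolved` and are not counted.
#'
#' @param history data.frame with columns `frame` and `area_px` (the track's
#'   per-frame record, frames ascending).
#' @param params a [TrackingParams-class].
#' @param last_frame index of the last frame of the stack.
#' @param first_frame index of the first frame (default 1).
#' @return One of `"viable"`, `"static"`, `"unresolved"`.
#' @export
classifyViability <- function(history, params = TrackingParams(),
                              last_frame, first_frame = 1L) {
  if (!nrow(history)) stop("empty track history")
  a <- history$area_px
  birth <- history$frame[1L]
  run <- if (length(a) == 1L) 1L else {
    r <- rle(diff(a) >= 0)
    ok <- r$lengths[r$values]
    if (length(ok)) max(ok) + 1L else 1L
  }
  grew <- max(a) >= params@growth_factor_min * a[1L]
  if (grew && run >= params@min_growth_frames) return("viable")
  if (birth == first_frame && max(a) < params@growth_factor_min * a[1L])
    return("static")
  "unresolved"
}

# contingency of foreground labels between two label matrices
.overlap_pairs <- function(prev, cur) {
  sel <- prev > 0L & cur > 0L
  if (!any(sel))
    return(data.frame(prev = integer(), cur = integer(), npix = integer()))
  p <- prev[sel]; cc <- cur[sel]
  key <- as.numeric(p) * (max(cc) + 1) + cc
  u <- which(!duplicated(key))
  m <- match(key, key[u])
  data.frame(prev = p[u], cur = cc[u], npix = tabulate(m, nbins = length(u)))
}

#' Track colonies through a frame stack
#'
#' Runs segmentation on every frame and links the detections into tracks:
#' one-to-one continuation by greedy nearest-neighbour linking within a
#' tight gate (with a one-frame grace period), fusion handling when a single
#' component overlaps several tracks' previous masks (the tracks keep their
#' identities and their counts), doublet resolution from temporal evidence,
#' and growth-based viability classification of every track with full-stack
#' hindsight.
#'
#' @param stack a [FrameStack-class].
#' @param seg_params a [SegmentationParams-class].
#' @param track_params a [TrackingParams-class].
#' @param geometry a [PlateGeometry-class]; when `NULL`, a centred plate
#'   filling 90\% of the sensor is assumed.
#' @param background_level background intensity; when `NULL`, estimated from
#'   the first frame via [estimateBackground()].
#' @return A [ColonyTrackSet-class].
#' @seealso [countSeries()], [segmentFrame()]
#' @export
trackColonies <- function(stack, seg_params = SegmentationParams(),
                          track_params = TrackingParams(), geometry = NULL,
                          background_level = NULL) {
  stopifnot(is(stack, "FrameStack"))
  n <- length(stack@frames)
  if (n < 1L) stop("empty frame stack")
  d <- dim(stack@frames[[1L]])
  if (is.null(geometry)) {
    ctr <- (d + 1) / 2
    geometry <- PlateGeometry(ctr, 0.45 * min(d))
  }
  if (is.null(background_level))
    background_level <- estimateBackground(stack@frames[[1L]], geometry)

  # track state (parallel vectors)
  id <- integer(); birth <- integer(); last_seen <- integer()
  cur_label <- integer()        # label in the most recent frame, NA if missed
  row <- numeric(); col <- numeric(); area <- numeric()
  missed <- integer(); ended <- logical(); fgroup <- integer()
  rim <- logical(); extra_mult <- integer()
  next_id <- 1L; next_group <- 1L
  fus <- list(); recs <- vector("list", n)
  prev_labs <- NULL

  new_tracks <- function(tab, f) {
    k <- nrow(tab)
    if (!k) return()
    ids <- next_id - 1L + seq_len(k)
    next_id <<- next_id + k
    id <<- c(id, ids); birth <<- c(birth, rep(f, k))
    last_seen <<- c(last_seen, rep(f, k)); cur_label <<- c(cur_label, tab$label)
    row <<- c(row, tab$row); col <<- c(col, tab$col)
    area <<- c(area, tab$area_px); missed <<- c(missed, rep(0L, k))
    ended <<- c(ended, rep(FALSE, k)); fgroup <<- c(fgroup, rep(NA_integer_, k))
    rim <<- c(rim, tab$rim_flag); extra_mult <<- c(extra_mult, rep(1L, k))
    data.frame(track = ids, frame = f, area_px = tab$area_px, row = tab$row,
               col = tab$col, mean_depth = tab$mean_depth, label = tab$label,
               rmin = tab$rmin, rmax = tab$rmax, cmin = tab$cmin,
               cmax = tab$cmax)
  }

  for (f in seq_len(n)) {
    seg <- segmentFrame(stack@frames[[f]], background_level, seg_params,
                        geometry)
    tab <- seg$table; labs <- seg$labels
    frame_recs <- NULL
    det_used <- rep(FALSE, nrow(tab))
    if (f > 1L) {
      alive <- which(!ended)
      # overlap of current components with the previous frame's components,
      # mapped to the tracks seen there
      ov <- .overlap_pairs(prev_labs, labs)
      trk_of_prev <- rep(NA_integer_, max(c(prev_labs, 0L)))
      seen_prev <- which(!ended & !is.na(cur_label) & last_seen == f - 1L)
      owned_prev <- cur_label[seen_prev]  # previous-frame labels with owners
      trk_of_prev[owned_prev] <- seen_prev
      ov$track <- if (nrow(ov)) trk_of_prev[ov$prev] else integer()
      ov <- ov[!is.na(ov$track), , drop = FALSE]
      # each overlapped track claims the current component it overlaps most
      claimed_comp <- rep(NA_integer_, length(id))
      if (nrow(ov)) {
        ov <- ov[order(ov$track, -ov$npix), ]
        first <- !duplicated(ov$track)
        claimed_comp[ov$track[first]] <- ov$cur[first]
      }
      upd_trk <- which(!is.na(claimed_comp))
      # fusion: >= 2 tracks claiming one component (not yet one group)
      if (length(upd_trk)) {
        by_comp <- split(upd_trk, claimed_comp[upd_trk])
        for (cl in names(by_comp)) {
          mem <- by_comp[[cl]]
          if (length(mem) >= 2L) {
            gg <- unique(fgroup[mem])
            if (length(gg) > 1L || anyNA(gg)) {
              g <- next_group; next_group <- next_group + 1L
              fgroup[mem] <- g
              fus[[length(fus) + 1L]] <- data.frame(
                frame = f, fusion_group = g,
                component_label = as.integer(cl),
                track_ids = paste(id[mem], collapse = ","))
            } else fgroup[mem] <- gg
          }
        }
        # update claimed tracks from their components
        comp_row <- match(claimed_comp[upd_trk], tab$label)
        last_seen[upd_trk] <- f
        cur_label[upd_trk] <- tab$label[comp_row]
        row[upd_trk] <- tab$row[comp_row]
        col[upd_trk] <- tab$col[comp_row]
        area[upd_trk] <- tab$area_px[comp_row]
        missed[upd_trk] <- 0L
        det_used[comp_row] <- TRUE
        frame_recs <- data.frame(track = id[upd_trk], frame = f,
                                 area_px = tab$area_px[comp_row],
                                 row = tab$row[comp_row],
                                 col = tab$col[comp_row],
                                 mean_depth = tab$mean_depth[comp_row],
                                 label = tab$label[comp_row],
                                 rmin = tab$rmin[comp_row],
                                 rmax = tab$rmax[comp_row],
                                 cmin = tab$cmin[comp_row],
                                 cmax = tab$cmax[comp_row])
        # doublet evidence: previous-frame components inside a claimed
        # component that belonged to no track
        if (nrow(ov)) {
          all_prev <- .overlap_pairs(prev_labs, labs)
          extra <- all_prev[!(all_prev$prev %in% owned_prev), , drop = FALSE]
          if (nrow(extra)) {
            addl <- table(extra$cur)
            for (cl in names(addl)) {
              tt <- upd_trk[claimed_comp[upd_trk] == as.integer(cl)]
              if (length(tt) == 1L)
                extra_mult[tt] <- max(extra_mult[tt],
                                      1L + as.integer(addl[[cl]]))
            }
          }
        }
      }
      # distance linking for the rest
      free_trk <- setdiff(which(!ended), upd_trk)
      free_det <- which(!det_used)
      if (length(free_trk) && length(free_det)) {
        asg <- linkDetections(data.frame(row = row[free_trk],
                                         col = col[free_trk]),
                              tab[free_det, c("row", "col")],
                              track_params@max_link_px)
        hit <- which(!is.na(asg))
        if (length(hit)) {
          ti <- free_trk[asg[hit]]; di <- free_det[hit]
          last_seen[ti] <- f
          cur_label[ti] <- tab$label[di]
          row[ti] <- tab$row[di]; col[ti] <- tab$col[di]
          area[ti] <- tab$area_px[di]; missed[ti] <- 0L
          det_used[di] <- TRUE
          frame_recs <- rbind(frame_recs,
            data.frame(track = id[ti], frame = f, area_px = tab$area_px[di],
                       row = tab$row[di], col = tab$col[di],
                       mean_depth = tab$mean_depth[di], label = tab$label[di],
                       rmin = tab$rmin[di], rmax = tab$rmax[di],
                       cmin = tab$cmin[di], cmax = tab$cmax[di]))
        }
      }
      # unmatched tracks: grace, then end
      miss_trk <- which(!ended & last_seen < f)
      cur_label[miss_trk] <- NA_integer_
      missed[miss_trk] <- missed[miss_trk] + 1L
      ended[miss_trk[missed[miss_trk] > track_params@grace_frames]] <- TRUE
    }
    # unmatched detections spawn tracks
    nr <- new_tracks(tab[!det_used, , drop = FALSE], f)
    recs[[f]] <- rbind(frame_recs, nr)
    prev_labs <- labs
  }

  all_recs <- do.call(rbind, recs)
  status <- ifelse(!is.na(fgroup), "fused", ifelse(ended, "ended", "active"))
  info <- data.frame(track_id = id, birth_frame = birth, last_frame = last_seen,
                     status = status,
                     viability = rep(NA_character_, length(id)),
                     fusion_group = fgroup, multiplicity = extra_mult,
                     rim_flag = rim)
  ord <- order(info$track_id)
  info <- info[ord, , drop = FALSE]
  rownames(info) <- NULL
  history <- if (nrow(info)) {
    sp <- split(all_recs[, c("frame", "area_px", "row", "col", "mean_depth",
                             "label", "rmin", "rmax", "cmin", "cmax")],
                factor(all_recs$track, levels = info$track_id))
    lapply(sp, function(h) { h <- h[order(h$frame), ]; rownames(h) <- NULL; h })
  } else list()
  info$viability <- vapply(seq_len(nrow(info)), function(j)
    classifyViability(history[[j]], track_params, last_frame = n), character(1))
  # late births with too little evidence stay unresolved
  late <- info$birth_frame > n - as.integer(track_params@confirm_frames) &
          info$viability != "viable"
  info$viability[late] <- "unresolved"
  fusions <- if (length(fus)) do.call(rbind, fus) else
    data.frame(frame = integer(), fusion_group = integer(),
               component_label = integer(), track_ids = character())
  new("ColonyTrackSet", info = info, history = unname(history),
      fusions = fusions, times_h = stack@times_h)
}

#' Colony-count time series from tracked colonies
#'
#' `N_i` is the number of registered viable colonies at capture time `i`:
#' each track classified viable contributes its multiplicity from its birth
#' frame onward; fused tracks are counted individually, so `N_i` does not
#' drop when shadows merge; static particles and unresolved tracks
#' contribute nothing.
#'
#' @param tracks a [ColonyTrackSet-class].
#' @param times_h capture times; defaults to the times recorded in `tracks`.
#' @return A [CountSeries-class].
#' @export
countSeries <- function(tracks, times_h = NULL) {
  stopifnot(is(tracks, "ColonyTrackSet"))
  if (is.null(times_h)) times_h <- tracks@times_h
  n <- length(times_h)
  if (!n) stop("no capture times")
  info <- tracks@info
  v <- info[info$viability == "viable", , drop = FALSE]
  cnt <- integer(n)
  if (nrow(v))
    for (i in seq_len(n))
      cnt[i] <- sum(v$multiplicity[v$birth_frame <= i])
  CountSeries(times_h, cnt)
}
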