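# On-disk layout:  root/<plate_id>/index.json
#                  root/<plate_id>/colonies/track_<id>.tif
# One multi-page 16-bit TIFF per colony plus one JSON index per plate keeps
# the store human-inspectable; crops can be opened in any image viewer.
.STORE_VERSION <- "1"

.plate_dir <- function(root, plate_id) file.path(root, as.character(plate_id))

#' Record every colony's time-lapse image history
#'
#' Writes, for each track, the series of sub-images around the colony from
#' its birth frame to its last frame (one multi-page 16-bit grayscale TIFF
#' per colony), plus a JSON index holding the track metadata. The crop
#' window is the track's final bounding box grown by `crop_margin_px`,
#' recentred on the per-frame centroid and clamped at the image edges.
#' Re-running overwrites the plate entry deterministically.
#'
#' @param plate_id plate identifier (used as the directory name).
#' @param stack the [FrameStack-class] the tracks were derived from.
#' @param tracks a [ColonyTrackSet-class].
#' @param crop_margin_px margin beyond the final bounding box (px).
#' @param root store root directory (created if needed).
#' @return The index, invisibly (a list mirroring `index.json`).
#' @seealso [retrieveColony()], [retrieveLateColonies()]
#' @export
recordPlate <- function(plate_id, stack, tracks, crop_margin_px = 10L,
                        root) {
  stopifnot(is(stack, "FrameStack"), is(tracks, "ColonyTrackSet"))
  pd <- .plate_dir(root, plate_id)
  cd <- file.path(pd, "colonies")
  if (dir.exists(pd)) unlink(pd, recursive = TRUE)
  if (!dir.create(cd, recursive = TRUE, showWarnings = FALSE) &&
      !dir.exists(cd))
    stop("cannot create store directory: ", cd)
  d <- if (length(stack@frames)) dim(stack@frames[[1L]]) else c(0L, 0L)
  info <- tracks@info
  colonies <- vector("list", nrow(info))
  for (j in seq_len(nrow(info))) {
    h <- tracks@history[[j]]
    if (any(h$frame > length(stack@frames)))
      stop("track ", info$track_id[j], " references a frame beyond the stack")
    last <- nrow(h)
    hr <- ceiling((h$rmax[last] - h$rmin[last]) / 2) + crop_margin_px
    hc <- ceiling((h$cmax[last] - h$cmin[last]) / 2) + crop_margin_px
    pages <- vector("list", nrow(h))
    for (k in seq_len(nrow(h))) {
      r0 <- round(h$row[k]) - hr; r1 <- round(h$row[k]) + hr
      if (r0 < 1L) { r1 <- r1 + (1L - r0); r0 <- 1L }
      if (r1 > d[1L]) { r0 <- r0 - (r1 - d[1L]); r1 <- d[1L] }
      c0 <- round(h$col[k]) - hc; c1 <- round(h$col[k]) + hc
      if (c0 < 1L) { c1 <- c1 + (1L - c0); c0 <- 1L }
      if (c1 > d[2L]) { c0 <- c0 - (c1 - d[2L]); c1 <- d[2L] }
      pages[[k]] <- stack@frames[[h$frame[k]]][max(1L, r0):r1,
                                               max(1L, c0):c1, drop = FALSE]
    }
    file_k <- file.path("colonies", sprintf("track_%06d.tif", info$track_id[j]))
    tiff::writeTIFF(pages, file.path(pd, file_k), bits.per.sample = 16L,
                    compression = "none")
    colonies[[j]] <- list(
      track_id = info$track_id[j], file = file_k,
      birth_frame = info$birth_frame[j], last_frame = info$last_frame[j],
      frame_indices = h$frame, viability = info$viability[j],
      fusion_group = info$fusion_group[j],
      multiplicity = info$multiplicity[j], rim_flag = info$rim_flag[j])
  }
  index <- list(version = .STORE_VERSION, plate_id = as.character(plate_id),
                times_h = stack@times_h, pixel_size_um = stack@pixel_size_um,
                colonies = colonies)
  jsonlite::write_json(index, file.path(pd, "index.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(index)
}

.read_index <- function(root, plate_id) {
  f <- file.path(.plate_dir(root, plate_id), "index.json")
  if (!file.exists(f)) stop("plate not found in store: ", plate_id)
  jsonlite::read_json(f, simplifyVector = FALSE)
}

.colony_record <- function(root, plate_id, entry) {
  f <- file.path(.plate_dir(root, plate_id), entry$file)
  if (!file.exists(f)) stop("missing crop file: ", f)
  crops <- tiff::readTIFF(f, all = TRUE)
  if (!is.list(crops)) crops <- list(crops)
  list(plate_id = as.character(plate_id), track_id = entry$track_id,
       frame_indices = unlist(entry$frame_indices), crops = crops,
       metadata = list(viability = entry$viability,
                       birth_frame = entry$birth_frame,
                       last_frame = entry$last_frame,
                       fusion_group = entry$fusion_group,
                       multiplicity = entry$multiplicity,
                       rim_flag = entry$rim_flag))
}

#' Retrieve one colony's recorded image history
#'
#' @param root store root directory.
#' @param plate_id plate identifier.
#' @param track_id track identifier within the plate.
#' @return A colony record: `plate_id`, `track_id`, `frame_indices`,
#'   `crops` (list of grayscale matrices, one per recorded frame) and
#'   `metadata`.
#' @export
retrieveColony <- function(root, plate_id, track_id) {
  idx <- .read_index(root, plate_id)
  ids <- vapply(idx$colonies, function(e) e$track_id, numeric(1))
  j <- match(track_id, ids)
  if (is.na(j)) stop("colony not found in store: ", track_id)
  .colony_record(root, plate_id, idx$colonies[[j]])
}

#' Retrieve the colonies that appeared after the steady call
#'
#' Returns the records of all viable colonies whose birth time is later
#' than `t_stdy_h` — the colonies responsible for a late increase of the
#' count (typically retarded rim colonies), kept retrievable precisely so
#' that a discrepancy between the rapid and the confirmed count can be
#' elucidated from the stored images.
#'
#' @param root store root directory.
#' @param plate_id plate identifier.
#' @param t_stdy_h steady-level decision time (h).
#' @return A list of colony records (possibly empty).
#' @export
retrieveLateColonies <- function(root, plate_id, t_stdy_h) {
  idx <- .read_index(root, plate_id)
  times <- unlist(idx$times_h)
  out <- list()
  for (e in idx$colonies) {
    if (!identical(e$viability, "viable")) next
    if (times[e$birth_frame] > t_stdy_h)
      out[[length(out) + 1L]] <- .colony_record(root, plate_id, e)
  }
  out
}
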