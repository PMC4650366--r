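#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' @param stack a [FrameStack-class].
#' @param path output TIFF path.
#' @param times_path optional sidecar CSV path receiving the capture times
#'   (columns `frame_index`, `time_h`; `frame_index` starts at 0).
#' @return `path`, invisibly.
#' @export
writeFrameStack <- function(stack, path, times_path = NULL) {
  stopifnot(is(stack, "FrameStack"))
  tiff::writeTIFF(stack@frames, path, bits.per.sample = 16L,
                  compression = "none")
  if (!is.null(times_path))
    utils::write.csv(data.frame(frame_index = seq_along(stack@times_h) - 1L,
                                time_h = stack@times_h),
                     times_path, row.names = FALSE)
  invisible(path)
}

.read_gray <- function(f) {
  x <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
       else tiff::readTIFF(f)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

#' Read a frame stack from a TIFF stack or a frame directory
#'
#' Accepts either a multi-page TIFF (one page per frame) or a directory of
#' per-frame TIFF/PNG images, read in lexicographic filename order. Capture
#' times come from a sidecar CSV (`frame_index`, `time_h`) or from a constant
#' frame interval.
#'
#' @param path TIFF file or directory of frames.
#' @param times_csv optional CSV with columns `frame_index`, `time_h`.
#' @param interval_h constant frame interval (h), used when `times_csv` is
#'   not given.
#' @param pixel_size_um physical pixel size (um); default is the standard
#'   100 mm / 1536 px geometry.
#' @return A [FrameStack-class].
#' @export
readFrameStack <- function(path, times_csv = NULL, interval_h = 1,
                           pixel_size_um = pixelSizeUm(100, 1536)) {
  if (dir.exists(path)) {
    ff <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                          ignore.case = TRUE, full.names = TRUE))
    if (!length(ff)) stop("no TIFF/PNG frames found in ", path)
    frames <- lapply(ff, .read_gray)
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    frames <- tiff::readTIFF(path, all = TRUE)
    frames <- lapply(frames, function(x)
      if (length(dim(x)) == 3L) x[, , 1L] else x)
  }
  if (!is.null(times_csv)) {
    tt <- utils::read.csv(times_csv)
    if (!all(c("frame_index", "time_h") %in% names(tt)))
      stop("times CSV must have columns frame_index, time_h")
    times <- tt$time_h[order(tt$frame_index)]
    if (length(times) != length(frames))
      stop("times CSV length does not match number of frames")
  } else {
    times <- (seq_along(frames) - 1) * interval_h
  }
  FrameStack(frames, times, pixel_size_um)
}

#' Write / read a simulator ground-truth table
#'
#' @param truth ground-truth data.frame from [simulatePlate()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read), invisibly/visibly.
#' @export
writeGroundTruth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) utils::read.csv(path)

#' Read a colony-count series from CSV
#'
#' @param path CSV with columns `time_h` and `n`.
#' @return A [CountSeries-class].
#' @export
readCountSeries <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time_h", "n") %in% names(x)))
    stop("count series CSV must have columns time_h, n")
  CountSeries(x$time_h, x$n)
}

#' @rdname readCountSeries
#' @param series a [CountSeries-class].
#' @export
writeCountSeries <- function(series, path) {
  stopifnot(is(series, "CountSeries"))
  utils::write.csv(data.frame(time_h = series@times_h, n = series@counts),
                   path, row.names = FALSE)
  invisible(path)
}

# config <-> JSON echo for provenance
.config_to_list <- function(config) {
  sl <- slotNames(config)
  out <- lapply(sl, function(s) slot(config, s))
  names(out) <- sl
  out
}

#' Echo a simulation configuration to JSON
#'
#' @param config a [SimulationConfig-class].
#' @param path JSON path.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(.config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(SimulationConfig, x)
}
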