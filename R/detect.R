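#' Physical pixel size of the imaging field
#'
#' With the standard field of 100 mm imaged on 1536 pixels, one pixel is
#' 65.1 um; the integer pixel size quoted for the system (65 um) is the
#' truncation of this value. One pixel is the spatial precision of the
#' analysis and the colony recognition threshold.
#'
#' @param field_mm side length of the imaged field (mm).
#' @param sensor_px number of pixels along that side.
#' @return Pixel side length in micrometres.
#' @examples
#' pixelSizeUm(100, 1536)   # 65.104...
#' @export
pixelSizeUm <- function(field_mm, sensor_px) {
  if (!is.numeric(sensor_px) || length(sensor_px) != 1L || sensor_px <= 0)
    stop("sensor_px must be a positive scalar")
  if (!is.numeric(field_mm) || length(field_mm) != 1L || field_mm <= 0)
    stop("field_mm must be a positive scalar")
  1000 * field_mm / sensor_px
}

#' Binary mask of the plate interior
#'
#' @param geometry a [PlateGeometry-class].
#' @param shape integer length-2, (nrow, ncol) of the target image.
#' @return Logical matrix, TRUE exactly where the pixel centre lies within
#'   `plate_radius_px` of the plate centre. The circle is clipped at the
#'   image edges; a radius of 0 is a degenerate plate with no interior
#'   (all-false mask). The plate centre must lie inside the image.
#' @export
buildPlateMask <- function(geometry, shape) {
  stopifnot(is(geometry, "PlateGeometry"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape <= 0L))
    stop("shape must be two positive integers")
  ctr <- geometry@center_px
  r <- geometry@plate_radius_px
  if (ctr[1L] < 0.5 || ctr[1L] > shape[1L] + 0.5 ||
      ctr[2L] < 0.5 || ctr[2L] > shape[2L] + 0.5)
    stop("plate geometry exceeds image bounds: center outside the image")
  if (r <= 0) return(matrix(FALSE, shape[1L], shape[2L]))
  dr2 <- (seq_len(shape[1L]) - ctr[1L])^2
  dc2 <- (seq_len(shape[2L]) - ctr[2L])^2
  outer(dr2, dc2, "+") <= r^2
}

#' Robust background level of a plate
#'
#' The median intensity inside the plate mask of the first frame. Using the
#' first frame (and the median) keeps the reference immune to colonies
#' darkening the plate later in the run.
#'
#' @param frame0 grayscale matrix of the first frame.
#' @param geometry a [PlateGeometry-class].
#' @return Scalar background intensity.
#' @export
estimateBackground <- function(frame0, geometry) {
  stopifnot(is.matrix(frame0))
  m <- buildPlateMask(geometry, dim(frame0))
  if (!any(m)) stop("plate mask is empty; cannot estimate background")
  stats::median(frame0[m])
}

# 8-connectivity labelling: EBImage::bwlabel is 4-connected; merge labels of
# diagonally adjacent pixels with a union-find over label pairs.
.label_components <- function(fg, connectivity) {
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # down-right diagonal
    a2 <- lab[-1L, -nc]; b2 <- lab[-nr, -1L]   # up-right diagonal
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                          cbind(a2[keep2], b2[keep2])))
    if (nrow(pairs)) {
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  lab
}

#' Segment candidate objects in one frame
#'
#' A pixel is foreground when its shadow depth (background level minus
#' intensity) reaches `depth_threshold` and it lies inside the plate mask.
#' Connected foreground components (8-connectivity by default) of at least
#' `min_area_px` pixels become detections; the default minimum area of one
#' pixel implements the one-pixel colony recognition threshold. Components
#' are relabelled 1..n in deterministic raster order (order of their first
#' pixel in column-major scan), so segmentation is a pure function of the
#' pixel values and parameters.
#'
#' @param image grayscale matrix with values in [0, 1].
#' @param background_level scalar background intensity (see
#'   [estimateBackground()]).
#' @param params a [SegmentationParams-class].
#' @param geometry a [PlateGeometry-class].
#' @return A list with `table`, a data.frame of detections (`label`, `row`,
#'   `col` centroid, `area_px`, `mean_depth`, `rmin`/`rmax`/`cmin`/`cmax`
#'   bounding box, `rim_flag`), and `labels`, the integer label matrix
#'   (0 = background) serving as the detection masks.
#' @export
segmentFrame <- function(image, background_level, params = SegmentationParams(),
                         geometry) {
  stopifnot(is(params, "SegmentationParams"), is(geometry, "PlateGeometry"))
  if (!is.matrix(image) || !length(image)) stop("image must be a non-empty matrix")
  if (min(image) < 0 || max(image) > 1) stop("image values must be in [0, 1]")
  mask <- buildPlateMask(geometry, dim(image))
  fg <- ((background_level - image) >= params@depth_threshold) & mask
  empty <- list(table = data.frame(label = integer(), row = numeric(),
                                   col = numeric(), area_px = integer(),
                                   mean_depth = numeric(), rmin = integer(),
                                   rmax = integer(), cmin = integer(),
                                   cmax = integer(), rim_flag = logical()),
                labels = matrix(0L, nrow(image), ncol(image)))
  if (!any(fg)) return(empty)
  lab <- .label_components(fg, params@connectivity)
  idx <- which(lab > 0L)
  ids <- lab[idx]
  area <- tabulate(ids)
  keep <- which(area >= params@min_area_px)
  if (!length(keep)) return(empty)
  # deterministic raster order: rank labels by first pixel (column-major)
  first_px <- rep(NA_integer_, max(ids))
  first_px[ids[length(idx):1L]] <- idx[length(idx):1L]  # overwritten by earliest
  keep <- keep[order(first_px[keep])]
  relab <- rep(0L, length(area))
  relab[keep] <- seq_along(keep)
  lab[idx] <- relab[ids]
  idx <- idx[relab[ids] > 0L]
  ids <- lab[idx]
  rows <- ((idx - 1L) %% nrow(image)) + 1L
  cols <- ((idx - 1L) %/% nrow(image)) + 1L
  depth <- background_level - image[idx]
  n <- length(keep)
  f <- factor(ids, levels = seq_len(n))  # keep numeric label order
  tab <- data.frame(
    label = seq_len(n),
    row = as.numeric(tapply(rows, f, mean)),
    col = as.numeric(tapply(cols, f, mean)),
    area_px = as.integer(tabulate(ids, nbins = n)),
    mean_depth = as.numeric(tapply(depth, f, mean)),
    rmin = as.integer(tapply(rows, f, min)),
    rmax = as.integer(tapply(rows, f, max)),
    cmin = as.integer(tapply(cols, f, min)),
    cmax = as.integer(tapply(cols, f, max))
  )
  rr <- sqrt((tab$row - geometry@center_px[1L])^2 +
             (tab$col - geometry@center_px[2L])^2)
  tab$rim_flag <- rr >= (1 - geometry@rim_fraction) * geometry@plate_radius_px
  list(table = tab, labels = lab)
}
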