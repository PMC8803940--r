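#' Bounding boxes
#'
#' Axis-aligned boxes in voxel coordinates, 0-based with half-open extents
#' \code{[start, start + lengths)}.
#'
#' @param start integer triple (i0, j0, k0), each >= 0.
#' @param lengths integer triple of positive edge lengths.
#' @return a \code{bounding_box} list.
#' @export
bounding_box <- function(start, lengths) {
  start <- as.integer(round(start))
  lengths <- as.integer(round(lengths))
  stopifnot(length(start) == 3, length(lengths) == 3,
            all(start >= 0), all(lengths > 0))
  structure(list(start = start, lengths = lengths), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat("bounding box: start (", paste(x$start, collapse = ", "),
      "), lengths (", paste(x$lengths, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Tight bounding box of the labeled brain
#'
#' The tightest axis-aligned box containing every non-Unknown voxel of the
#' mask; this is the regression target of the cropping network.
#'
#' @param mask a \code{label_mask} with at least one non-Unknown voxel.
#' @return a \code{\link{bounding_box}}.
#' @export
bbox_target <- function(mask) {
  stopifnot(is_label_mask(mask))
  nz <- which(mask$labels != unknown_id(mask$scheme), arr.ind = TRUE)
  if (nrow(nz) == 0) stop("mask contains no non-Unknown voxels")
  lo <- apply(nz, 2, min)
  hi <- apply(nz, 2, max)
  bounding_box(start = lo - 1L, lengths = hi - lo + 1L)
}

#' Crop a volume or mask to a bounding box
#'
#' Label masks are cropped without interpolation.
#'
#' @param x a \code{brain_volume} or \code{label_mask}.
#' @param box a \code{\link{bounding_box}} lying within \code{x}.
#' @return the cropped object of the same kind.
#' @export
crop <- function(x, box) {
  stopifnot(inherits(box, "bounding_box"))
  d <- vol_shape(x)
  if (any(box$start + box$lengths > d))
    stop("bounding box exceeds the volume extent")
  ii <- seq.int(box$start[1] + 1L, box$start[1] + box$lengths[1])
  jj <- seq.int(box$start[2] + 1L, box$start[2] + box$lengths[2])
  kk <- seq.int(box$start[3] + 1L, box$start[3] + box$lengths[3])
  if (is_volume(x)) {
    as_volume(x$data[ii, jj, kk, drop = FALSE], spacing = x$spacing,
              orientation = x$orientation)
  } else {
    as_label_mask(x$labels[ii, jj, kk, drop = FALSE], x$scheme,
                  spacing = x$spacing, orientation = x$orientation)
  }
}

#' Paste a cropped block back into a full-extent array
#'
#' The inverse of \code{\link{crop}}: voxels outside the box are set to
#' \code{fill} (for predictions, the Unknown label).
#'
#' @param x a \code{brain_volume} or \code{label_mask} of the box's shape.
#' @param box the \code{\link{bounding_box}} it was cropped with.
#' @param full_shape the target extent.
#' @param fill fill value outside the box.
#' @return the embedded object of the same kind as \code{x}.
#' @export
uncrop <- function(x, box, full_shape, fill = 0L) {
  stopifnot(inherits(box, "bounding_box"))
  d <- vol_shape(x)
  stopifnot(all(d == box$lengths), all(box$start + box$lengths <= full_shape))
  ii <- seq.int(box$start[1] + 1L, box$start[1] + box$lengths[1])
  jj <- seq.int(box$start[2] + 1L, box$start[2] + box$lengths[2])
  kk <- seq.int(box$start[3] + 1L, box$start[3] + box$lengths[3])
  if (is_volume(x)) {
    out <- array(fill, full_shape)
    out[ii, jj, kk] <- x$data
    as_volume(out, spacing = x$spacing, orientation = x$orientation)
  } else {
    out <- array(as.integer(fill), full_shape)
    out[ii, jj, kk] <- x$labels
    as_label_mask(out, x$scheme, spacing = x$spacing,
                  orientation = x$orientation)
  }
}

#' Finalize the fixed-size crop box from a predicted 6-vector
#'
#' The regression network predicts \code{(start, lengths)} of the tight
#' brain box in the downsampled frame.  Its center is rescaled to full
#' resolution and a fixed-size box (the geometry's \code{crop_lengths}) is
#' placed around it; a box that would protrude is shifted, never shrunk, so
#' the output shape is always \code{crop_lengths}.
#'
#' @param predicted numeric 6-vector \code{(i0, j0, k0, di, dj, dk)} in the
#'   downsampled coordinate frame.
#' @param geometry a \code{\link{pipeline_geometry}}.
#' @param vol_shape full-resolution volume extent (default the geometry's
#'   input shape).
#' @return a \code{\link{bounding_box}} with \code{lengths ==
#'   geometry$crop_lengths}.
#' @export
finalize_bbox <- function(predicted, geometry,
                          vol_shape = geometry$input_shape) {
  stopifnot(length(predicted) == 6, all(is.finite(predicted)))
  fixed <- geometry$crop_lengths
  if (any(fixed > vol_shape))
    stop("fixed crop box larger than the volume")
  center_full <- (predicted[1:3] + predicted[4:6] / 2) / geometry$downsample
  start <- round(center_full - fixed / 2)
  start <- pmin(pmax(start, 0), vol_shape - fixed)
  bounding_box(start = start, lengths = fixed)
}
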