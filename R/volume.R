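#' Volume and label-mask containers
#'
#' A \code{brain_volume} is a 3D scalar intensity array together with its
#' voxel spacing (mm) and an axis-orientation code; a \code{label_mask} is a
#' 3D integer array tied to a \code{\link{label_scheme}}.  The internal
#' canonical orientation is \code{"RSA"}: array axis 1 runs left to right
#' (lateral), axis 2 inferior to superior, and axis 3 posterior to anterior,
#' so the anterior-posterior direction is always the third array axis.
#'
#' @param data 3D numeric array.
#' @param spacing voxel edge lengths in mm along the three axes.
#' @param orientation three-letter axis orientation code.
#' @return \code{as_volume}: a \code{brain_volume}.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), orientation = "RSA") {
  data <- unclass(data)
  if (length(dim(data)) != 3)
    stop("volume data must have exactly 3 axes, got ", length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive values")
  structure(list(data = data, spacing = spacing, orientation = orientation),
            class = "brain_volume")
}

#' @rdname as_volume
#' @param labels 3D integer array of label ids.
#' @param scheme a \code{\link{label_scheme}}; every value in \code{labels}
#'   must be one of its ids.
#' @export
as_label_mask <- function(labels, scheme, spacing = c(1, 1, 1),
                          orientation = "RSA") {
  labels <- unclass(labels)
  if (length(dim(labels)) != 3)
    stop("label mask must have exactly 3 axes, got ", length(dim(labels)))
  storage.mode(labels) <- "integer"
  present <- unique(as.vector(labels))
  bad <- setdiff(present, scheme$id)
  if (length(bad) > 0)
    stop("labels not in scheme: ", paste(sort(bad), collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive values")
  structure(list(labels = labels, scheme = scheme, spacing = spacing,
                 orientation = orientation),
            class = "label_mask")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("brain volume ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, orientation ", x$orientation, "\n", sep = "")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat("label mask ", paste(dim(x$labels), collapse = "x"),
      " voxels, ", length(setdiff(unique(as.vector(x$labels)),
                                  unknown_id(x$scheme))),
      " non-unknown labels present\n", sep = "")
  invisible(x)
}

is_volume <- function(x) inherits(x, "brain_volume")
is_label_mask <- function(x) inherits(x, "label_mask")

vol_shape <- function(x) {
  if (is_volume(x)) dim(x$data) else dim(x$labels)
}
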