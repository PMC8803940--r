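#' Read a NIfTI volume or label mask
#'
#' Volumes are reoriented on read to the canonical internal orientation
#' \code{"RSA"} (axis 1 lateral, axis 2 inferior-superior, axis 3
#' posterior-anterior), so that the anterior-posterior direction is always
#' the third array axis.  Label files are read without any interpolation or
#' rescaling and rounded to integers.
#'
#' @param path path to a 3D NIfTI-1 file (\code{.nii} or \code{.nii.gz}).
#' @param scheme if supplied, the file is interpreted as a label mask over
#'   this \code{\link{label_scheme}}.
#' @return a \code{\link{as_volume}[brain_volume]} or, with \code{scheme},
#'   a \code{label_mask}.
#' @export
read_nifti <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3)
    stop("expected a 3D image, got ", length(dim(img)), " dimensions: ", path)
  ori <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(ori) && nzchar(ori) && ori != "RSA")
    RNifti::orientation(img) <- "RSA"
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (is.null(scheme)) {
    as_volume(arr, spacing = spacing)
  } else {
    as_label_mask(round(arr), scheme, spacing = spacing)
  }
}

#' Write a volume or label mask to NIfTI
#'
#' @param x a \code{brain_volume} or \code{label_mask}.
#' @param path output path; compression follows the file extension.
#' @return \code{path}, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (is_volume(x)) {
    arr <- x$data
    sp <- x$spacing
  } else if (is_label_mask(x)) {
    arr <- x$labels
    sp <- x$spacing
  } else stop("x must be a brain_volume or label_mask")
  img <- RNifti::asNifti(arr)
  # canonical RSA affine: i -> +x (right), j -> +z (superior), k -> +y (anterior)
  aff <- rbind(c(sp[1], 0, 0, 0),
               c(0, 0, sp[3], 0),
               c(0, sp[2], 0, 0),
               c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}
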