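#' Pipeline geometry
#'
#' One object fixes every derived shape in the pipeline: the conformed input
#' grid, the fixed crop-box edge lengths, the downsampling factor feeding
#' the cropping network, and the subvolume shape and sampling step of the
#' segmentation stage (half and a quarter of the crop box, respectively, so
#' the default grid has 3 starts per axis and 27 overlapping subvolumes).
#'
#' The full-scale geometry conforms to a 256^3 1 mm grid with a fixed
#' 152 x 152 x 184 voxel box (15.2 cm lateral and inferior-superior, 18.4 cm
#' anterior-posterior); the desk-scale geometry shrinks everything by a
#' factor of four for CPU-sized experiments on 64^3 phantoms.
#'
#' @param input_shape conformed grid shape (3 integers).
#' @param crop_lengths fixed bounding-box edge lengths in voxels, each
#'   divisible by 4 so that the subvolume grid tiles evenly.
#' @param downsample factor applied to the conformed volume before the
#'   cropping network (default 0.5).
#' @param spacing_mm isotropic voxel size of the conformed grid.
#' @return a \code{pipeline_geometry} list with fields \code{input_shape},
#'   \code{crop_lengths}, \code{downsample}, \code{crop_input_shape},
#'   \code{sub_shape}, \code{step}, \code{spacing_mm}.
#' @export
pipeline_geometry <- function(input_shape = c(256, 256, 256),
                              crop_lengths = c(152, 152, 184),
                              downsample = 0.5, spacing_mm = 1) {
  input_shape <- as.integer(input_shape)
  crop_lengths <- as.integer(crop_lengths)
  stopifnot(length(input_shape) == 3, length(crop_lengths) == 3,
            all(input_shape > 0), all(crop_lengths > 0),
            downsample > 0, downsample <= 1)
  if (any(crop_lengths %% 4 != 0))
    stop("crop_lengths must be divisible by 4 to support the subvolume grid")
  if (any(crop_lengths > input_shape))
    stop("crop box larger than the input grid")
  structure(list(
    input_shape = input_shape,
    crop_lengths = crop_lengths,
    downsample = downsample,
    crop_input_shape = as.integer(round(input_shape * downsample)),
    sub_shape = crop_lengths %/% 2L,
    step = crop_lengths %/% 4L,
    spacing_mm = spacing_mm), class = "pipeline_geometry")
}

#' @rdname pipeline_geometry
#' @export
full_geometry <- function() pipeline_geometry()

#' @rdname pipeline_geometry
#' @export
desk_geometry <- function() {
  pipeline_geometry(input_shape = c(64, 64, 64), crop_lengths = c(40, 40, 48))
}

#' @export
print.pipeline_geometry <- function(x, ...) {
  cat("pipeline geometry: input ", paste(x$input_shape, collapse = "x"),
      ", crop box ", paste(x$crop_lengths, collapse = "x"),
      ", subvolumes ", paste(x$sub_shape, collapse = "x"),
      " step ", paste(x$step, collapse = "x"), "\n", sep = "")
  invisible(x)
}
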