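#' Online augmentation configuration
#'
#' With probability \code{rotate_prob}, a cropped volume/mask pair is
#' rotated identically: per-axis angles drawn uniformly from
#' \code{angle_range} degrees, about the volume center displaced by integer
#' voxel offsets drawn uniformly from \code{offset_range}.  Intensities are
#' interpolated trilinearly, labels by nearest neighbour.
#'
#' @param rotate_prob rotation probability in [0, 1] (default 0.3).
#' @param offset_range integer rotation-center offset bounds in voxels
#'   (default \code{c(-2, 2)}).
#' @param angle_range rotation-angle bounds in degrees (default
#'   \code{c(-1, 1)}).
#' @return an \code{augment_config} list.
#' @export
augment_config <- function(rotate_prob = 0.3, offset_range = c(-2L, 2L),
                           angle_range = c(-1, 1)) {
  stopifnot(rotate_prob >= 0, rotate_prob <= 1,
            length(offset_range) == 2, length(angle_range) == 2)
  structure(list(rotate_prob = rotate_prob,
                 offset_range = as.integer(offset_range),
                 angle_range = angle_range), class = "augment_config")
}

#' Randomly rotate a cropped volume/mask pair
#'
#' @param volume a cropped \code{brain_volume}.
#' @param mask the matching cropped \code{label_mask}.
#' @param cfg an \code{\link{augment_config}}.
#' @param seed random seed; the outcome is deterministic given it.
#' @return list with (possibly rotated) \code{volume} and \code{mask}.
#' @export
augment_pair <- function(volume, mask, cfg = augment_config(), seed = 1) {
  stopifnot(is_volume(volume), is_label_mask(mask))
  with_seed(seed, {
    if (stats::runif(1) >= cfg$rotate_prob)
      return(list(volume = volume, mask = mask))
    angles <- stats::runif(3, cfg$angle_range[1], cfg$angle_range[2])
    offset <- sample(seq.int(cfg$offset_range[1], cfg$offset_range[2]),
                     3, replace = TRUE)
    v <- rotate_array(volume$data, angles, offset, order = 1, fill = 0)
    l <- rotate_array(mask$labels, angles, offset, order = 0,
                      fill = unknown_id(mask$scheme))
    list(volume = as_volume(v, spacing = volume$spacing,
                            orientation = volume$orientation),
         mask = as_label_mask(l, mask$scheme, spacing = mask$spacing,
                              orientation = mask$orientation))
  })
}
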