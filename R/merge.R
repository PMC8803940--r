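#' Merge labels of a mask
#'
#' Voxelwise relabeling according to a merge map, e.g. collapsing left and
#' right hemisphere labels of the same structure into a single id, or
#' assigning one label to all ventricles.  Every label present in the mask
#' must have an entry in the map, and every target id must exist in the
#' mask's scheme; the returned mask carries the merged (restricted) scheme.
#'
#' @param m a \code{label_mask}.
#' @param merge_map named integer vector: names are old ids, values new ids.
#' @return a \code{label_mask} over the merged scheme.
#' @export
#' @examples
#' sch <- default_scheme()
#' m <- as_label_mask(array(c(0L, 35L, 36L, 36L, 0L, 0L, 0L, 35L), c(2, 2, 2)), sch)
#' merged <- merge_labels(m, c("0" = 0, "35" = 35, "36" = 35))
merge_labels <- function(m, merge_map) {
  stopifnot(is_label_mask(m))
  old_ids <- as.integer(names(merge_map))
  new_ids <- as.integer(merge_map)
  if (anyNA(old_ids)) stop("merge_map must be named by integer label ids")
  present <- unique(as.vector(m$labels))
  missing <- setdiff(present, old_ids)
  if (length(missing) > 0)
    stop("merge_map lacks entries for labels present in the mask: ",
         paste(sort(missing), collapse = ", "))
  bad_new <- setdiff(unique(new_ids), m$scheme$id)
  if (length(bad_new) > 0)
    stop("merge targets not in scheme: ", paste(sort(bad_new), collapse = ", "))
  lut <- rep(NA_integer_, max(old_ids) + 1L)
  lut[old_ids + 1L] <- new_ids
  relabeled <- array(lut[m$labels + 1L], dim = dim(m$labels))
  keep <- m$scheme$id %in% c(unique(new_ids), unknown_id(m$scheme))
  merged_scheme <- label_scheme(m$scheme$id[keep], m$scheme$name[keep],
                                m$scheme$macro_region[keep],
                                unknown_id = unknown_id(m$scheme))
  as_label_mask(relabeled, merged_scheme, spacing = m$spacing,
                orientation = m$orientation)
}
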