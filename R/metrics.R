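#' Segmentation similarity metrics
#'
#' Overlap and distance measures between two binary region masks:
#' \code{dsc} is the Dice similarity coefficient \code{2|A∩B|/(|A|+|B|)},
#' \code{iou} the Jaccard index \code{|A∩B|/|A∪B|} (related by
#' \code{iou = dsc/(2-dsc)}), both in [0, 1] with 1 for perfect overlap.
#' When both masks are empty the value is undefined and \code{NA} is
#' returned.
#'
#' @param a,b binary (logical or 0/1) arrays of identical shape.
#' @return a scalar in [0, 1], or \code{NA} if undefined.
#' @export
dsc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' @rdname dsc
#' @export
iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  u <- sum(a != 0 | b != 0)
  if (u == 0) return(NA_real_)
  sum(a != 0 & b != 0) / u
}

# boundary voxels of a binary 3D mask: inside the mask with at least one
# 6-neighbour outside (array borders count as outside)
boundary_voxels <- function(a) {
  a <- a != 0
  d <- dim(a)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, by) {
    idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    n <- d[ax]
    idx_dst[[ax]] <- if (by > 0) 2:n else 1:(n - 1)
    idx_src[[ax]] <- if (by > 0) 1:(n - 1) else 2:n
    nb <- array(FALSE, d)
    nb[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    acc & nb
  }
  for (ax in 1:3) for (by in c(-1, 1))
    interior <- shift_and(interior, ax, by)
  which(a & !interior, arr.ind = TRUE)
}

# largest (or percentile) of the nearest-neighbour distances from points in
# A to points in B, chunked to bound memory
directed_hd <- function(A, B, percentile = 1) {
  mins <- numeric(nrow(A))
  chunk <- max(1L, 2e6 %/% nrow(B))
  b2 <- rowSums(B^2)
  for (i0 in seq(1, nrow(A), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1, nrow(A))
    Ai <- A[ii, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), b2, `+`) - 2 * Ai %*% t(B)
    mins[ii] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  if (percentile >= 1) max(mins) else
    stats::quantile(mins, percentile, names = FALSE)
}

#' Hausdorff distance between two region masks
#'
#' Symmetric maximum of the directed nearest-neighbour distances between
#' the boundary voxels of the two masks, in mm (voxel coordinates scaled by
#' \code{spacing}).  A 95th-percentile variant is available via
#' \code{percentile = 0.95}.  Undefined (\code{NA}) if either mask is
#' empty.
#'
#' @inheritParams dsc
#' @param spacing voxel size in mm along each axis.
#' @param percentile 1 for the classical maximum (default), or a quantile
#'   in (0, 1) of the nearest-neighbour distances.
#' @return distance in mm, or \code{NA}.
#' @export
hausdorff <- function(a, b, spacing = c(1, 1, 1), percentile = 1) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  if (sum(a != 0) == 0 || sum(b != 0) == 0) return(NA_real_)
  A <- sweep(boundary_voxels(a), 2, spacing, `*`)
  B <- sweep(boundary_voxels(b), 2, spacing, `*`)
  max(directed_hd(A, B, percentile), directed_hd(B, A, percentile))
}

#' Relative volumetric difference
#'
#' \code{|V_g - V_p| / V_g}: the absolute volume error of the predicted
#' region relative to the ground-truth region volume.  Undefined
#' (\code{NA}) when the ground-truth volume is zero.
#'
#' @param v_g ground-truth region volume (voxel count or mm^3), > 0.
#' @param v_p predicted region volume on the same scale.
#' @return a nonnegative scalar, or \code{NA}.
#' @export
volumetric_difference <- function(v_g, v_p) {
  if (v_g <= 0) return(NA_real_)
  abs(v_g - v_p) / v_g
}

#' Per-region similarity metrics between two label masks
#'
#' Each non-Unknown region present in either mask is binarized and all
#' four metrics are computed, with \code{ref} acting as ground truth for
#' the volumetric difference.  Undefined values (empty region for the
#' Hausdorff distance, zero reference volume for VD) are returned as
#' \code{NA} and flagged, never silently dropped.
#'
#' @param ref reference \code{label_mask} (ground truth).
#' @param cmp comparison \code{label_mask}; same shape, scheme and
#'   spacing/orientation (masks are assumed co-registered; inconsistent
#'   geometry raises an error advising registration).
#' @param percentile Hausdorff variant, see \code{\link{hausdorff}}.
#' @return data frame with one row per region: \code{region_id},
#'   \code{region}, \code{macro_region}, \code{n_ref}, \code{n_cmp},
#'   \code{dsc}, \code{iou}, \code{hd_mm}, \code{vd}.
#' @export
per_region_metrics <- function(ref, cmp, percentile = 1) {
  stopifnot(is_label_mask(ref), is_label_mask(cmp))
  if (!all(vol_shape(ref) == vol_shape(cmp)))
    stop("mask shapes differ")
  if (!identical(ref$scheme$id, cmp$scheme$id))
    stop("masks use different label schemes")
  if (any(abs(ref$spacing - cmp$spacing) > 1e-6) ||
      !identical(ref$orientation, cmp$orientation))
    stop("mask geometries are inconsistent; co-register the volumes first")
  unk <- unknown_id(ref$scheme)
  ids <- sort(setdiff(union(unique(as.vector(ref$labels)),
                            unique(as.vector(cmp$labels))), unk))
  rows <- lapply(ids, function(id) {
    a <- ref$labels == id
    b <- cmp$labels == id
    n_ref <- sum(a); n_cmp <- sum(b)
    data.frame(
      region_id = id,
      region = ref$scheme$name[match(id, ref$scheme$id)],
      macro_region = ref$scheme$macro_region[match(id, ref$scheme$id)],
      n_ref = n_ref, n_cmp = n_cmp,
      dsc = dsc(a, b), iou = iou(a, b),
      hd_mm = hausdorff(a, b, ref$spacing, percentile),
      vd = volumetric_difference(n_ref, n_cmp),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
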