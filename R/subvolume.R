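#' Overlapping subvolume grid
#'
#' Start offsets of the overlapping subvolumes that tile a cropped volume.
#' Per axis the starts are \code{0, step, 2*step, ...} with the final start
#' forced to \code{extent - sub_shape}, so every voxel is covered by at
#' least one subvolume; the grid is the Cartesian product across axes.
#' With the full-scale defaults (extent 152x152x184, subvolume 76x76x92,
#' step 38x38x46) this yields 3 starts per axis and 27 subvolumes.
#'
#' @param extent cropped volume extent (3 integers).
#' @param sub_shape subvolume shape, \code{<= extent} per axis.
#' @param step sampling step, \code{<= sub_shape} per axis (overlap or
#'   exact tiling).
#' @return a \code{subvolume_grid}: list with \code{sub_shape}, \code{step},
#'   and \code{starts}, an n x 3 matrix of 0-based start triples.
#' @export
subvolume_grid <- function(extent, sub_shape, step) {
  extent <- as.integer(extent); sub_shape <- as.integer(sub_shape)
  step <- as.integer(step)
  stopifnot(length(extent) == 3, length(sub_shape) == 3, length(step) == 3,
            all(step >= 1), all(step <= sub_shape))
  if (any(sub_shape > extent))
    stop("sub_shape exceeds the volume extent")
  ax <- lapply(1:3, function(a) {
    s <- seq.int(0L, extent[a] - sub_shape[a], by = step[a])
    last <- extent[a] - sub_shape[a]
    if (s[length(s)] != last) s <- c(s, last)
    s
  })
  g <- as.matrix(expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]]))
  structure(list(sub_shape = sub_shape, step = step,
                 starts = unname(g), extent = extent),
            class = "subvolume_grid")
}

#' @export
print.subvolume_grid <- function(x, ...) {
  cat("subvolume grid: ", nrow(x$starts), " subvolumes of ",
      paste(x$sub_shape, collapse = "x"), " (step ",
      paste(x$step, collapse = "x"), ") over ",
      paste(x$extent, collapse = "x"), "\n", sep = "")
  invisible(x)
}

# extract one subvolume (plain array) from a 3D array; start is 0-based
extract_subvolume <- function(arr, start, sub_shape) {
  arr[seq.int(start[1] + 1L, start[1] + sub_shape[1]),
      seq.int(start[2] + 1L, start[2] + sub_shape[2]),
      seq.int(start[3] + 1L, start[3] + sub_shape[3]), drop = FALSE]
}

#' Merge per-subvolume scores over a grid
#'
#' Per-voxel class scores of all subvolumes are summed into a full-extent
#' accumulator and normalized by the per-voxel coverage count (how many
#' subvolumes contributed), implementing the "add and normalize the
#' overlapping parts" merge.
#'
#' @param sub_scores list with one 4D score array
#'   \code{(sub_shape, n_class)} per grid start, in grid order.
#' @param grid the \code{\link{subvolume_grid}}.
#' @param extent the cropped volume extent.
#' @return a \code{score_volume}: list with \code{scores} (4D array over
#'   \code{extent}) and \code{coverage} (3D count array, >= 1 everywhere).
#' @export
merge_predictions <- function(sub_scores, grid, extent = grid$extent) {
  stopifnot(inherits(grid, "subvolume_grid"))
  n <- nrow(grid$starts)
  if (length(sub_scores) != n)
    stop("need exactly one score array per grid start (",
         length(sub_scores), " != ", n, ")")
  K <- dim(sub_scores[[1]])[4]
  acc <- array(0, c(extent, K))
  cov <- array(0L, extent)
  ss <- grid$sub_shape
  for (m in seq_len(n)) {
    sc <- sub_scores[[m]]
    if (!all(dim(sc) == c(ss, K)))
      stop("score array ", m, " has wrong shape")
    st <- grid$starts[m, ]
    ii <- seq.int(st[1] + 1L, st[1] + ss[1])
    jj <- seq.int(st[2] + 1L, st[2] + ss[2])
    kk <- seq.int(st[3] + 1L, st[3] + ss[3])
    acc[ii, jj, kk, ] <- acc[ii, jj, kk, , drop = FALSE] + sc
    cov[ii, jj, kk] <- cov[ii, jj, kk] + 1L
  }
  if (any(cov < 1)) stop("grid does not cover the extent")
  acc <- acc / as.vector(cov)   # recycles over the class dimension
  structure(list(scores = acc, coverage = cov), class = "score_volume")
}

#' Class decision of a merged score volume
#'
#' Voxelwise argmax over the class dimension; ties break to the lowest
#' class index (deterministic).
#'
#' @param sv a \code{score_volume}.
#' @return 3D integer array of 1-based class indices.
#' @export
score_argmax <- function(sv) {
  d <- dim(sv$scores)
  m <- matrix(sv$scores, nrow = prod(d[1:3]), ncol = d[4])
  array(max.col(m, ties.method = "first"), d[1:3])
}
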