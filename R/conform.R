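# Conforming preprocessing: cubic-spline resampling to 1 mm isotropic,
# centered crop/pad to a fixed grid, and N(0,1) intensity normalization.

# Natural cubic spline interpolation with uniform knots, vectorized over the
# columns of y (n x m).  Knots sit at (0, h, 2h, ...); queries are clamped to
# the knot range.  Falls back to linear interpolation for n < 4.
spline_interp_cols <- function(y, h, xq) {
  n <- nrow(y)
  m <- ncol(y)
  xq <- pmin(pmax(xq, 0), (n - 1) * h)
  idx <- pmin(floor(xq / h) + 1, n - 1)
  u <- xq / h - (idx - 1)
  if (n < 4) {
    return(y[idx, , drop = FALSE] * (1 - u) + y[idx + 1, , drop = FALSE] * u)
  }
  # second derivatives via Thomas algorithm (natural end conditions)
  M <- matrix(0, n, m)
  d <- (y[3:n, , drop = FALSE] - 2 * y[2:(n - 1), , drop = FALSE] +
          y[1:(n - 2), , drop = FALSE]) / h
  nw <- n - 2
  b <- 2 * h / 3
  a <- h / 6
  cp <- numeric(nw)
  dp <- d
  cp[1] <- a / b
  dp[1, ] <- d[1, ] / b
  if (nw > 1) {
    for (i in 2:nw) {
      denom <- b - a * cp[i - 1]
      cp[i] <- a / denom
      dp[i, ] <- (d[i, ] - a * dp[i - 1, , drop = FALSE]) / denom
    }
    for (i in (nw - 1):1)
      dp[i, ] <- dp[i, ] - cp[i] * dp[i + 1, , drop = FALSE]
  }
  M[2:(n - 1), ] <- dp
  h2 <- h * h / 6
  w0 <- 1 - u
  y[idx, , drop = FALSE] * w0 + y[idx + 1, , drop = FALSE] * u +
    (w0^3 - w0) * h2 * M[idx, , drop = FALSE] +
    (u^3 - u) * h2 * M[idx + 1, , drop = FALSE]
}

# Resample one axis of a 3D array by cubic spline: original samples at
# spacing `h`, queries at index positions `qidx` (0-based, in units of the
# original grid when h = 1).
resample_axis <- function(arr, axis, h, qidx) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  y <- matrix(a, nrow = d[1])
  out <- spline_interp_cols(y, h, qidx * h)
  dim(out) <- c(length(qidx), d[2], d[3])
  aperm(out, order(perm))
}

crop_pad_center <- function(arr, shape, fill = 0) {
  d <- dim(arr)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= shape[ax]) {
      off <- (d[ax] - shape[ax]) %/% 2
      src[[ax]] <- seq.int(off + 1, off + shape[ax])
      dst[[ax]] <- seq_len(shape[ax])
    } else {
      off <- (shape[ax] - d[ax]) %/% 2
      src[[ax]] <- seq_len(d[ax])
      dst[[ax]] <- seq.int(off + 1, off + d[ax])
    }
  }
  out <- array(fill, shape)
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

#' Conform a volume to the pipeline grid
#'
#' Resamples to the target isotropic spacing with natural cubic spline
#' interpolation (separably along each axis), then center-crops or
#' zero-pads symmetrically to the target shape.  Already-conformed volumes
#' pass through unchanged.
#'
#' @param v a \code{brain_volume}.
#' @param shape target grid, default \code{c(256, 256, 256)}; desk-scale
#'   geometries pass their own (see \code{\link{pipeline_geometry}}).
#' @param spacing target voxel size in mm (scalar, isotropic), default 1.
#' @return a conformed \code{brain_volume}.
#' @export
conform <- function(v, shape = c(256, 256, 256), spacing = 1) {
  stopifnot(is_volume(v))
  d <- dim(v$data)
  if (any(d < 2)) stop("degenerate volume: extent < 2 voxels along an axis")
  arr <- v$data
  for (ax in 1:3) {
    if (abs(v$spacing[ax] - spacing) < 1e-9) next
    n_new <- max(2L, as.integer(round(d[ax] * v$spacing[ax] / spacing)))
    qidx <- (seq_len(n_new) - 1) * spacing / v$spacing[ax]
    arr <- resample_axis(arr, ax, 1, qidx)
  }
  if (!all(dim(arr) == shape)) arr <- crop_pad_center(arr, shape)
  as_volume(arr, spacing = rep(spacing, 3), orientation = v$orientation)
}

#' Downsample a conformed volume by a fixed factor
#'
#' Cubic-spline evaluation at index positions \code{(j-1)/factor}, so a
#' coordinate \code{x} in the downsampled frame maps to \code{x/factor} in
#' the full-resolution frame (shared origin).
#'
#' @param v a \code{brain_volume}.
#' @param factor scale factor in (0, 1]; default 0.5.
#' @return the downsampled \code{brain_volume}.
#' @export
downsample_volume <- function(v, factor = 0.5) {
  stopifnot(is_volume(v), factor > 0, factor <= 1)
  if (factor == 1) return(v)
  arr <- v$data
  d <- dim(arr)
  for (ax in 1:3) {
    n_new <- as.integer(round(d[ax] * factor))
    qidx <- (seq_len(n_new) - 1) / factor
    arr <- resample_axis(arr, ax, 1, qidx)
  }
  as_volume(arr, spacing = v$spacing / factor, orientation = v$orientation)
}

#' Normalize voxel intensities to zero mean and unit variance
#'
#' The statistics are computed over the full array including background.
#'
#' @param v a \code{brain_volume} with nonzero intensity variance.
#' @return a \code{brain_volume} with mean 0 and standard deviation 1.
#' @export
normalize_intensity <- function(v) {
  stopifnot(is_volume(v))
  s <- stats::sd(v$data)
  if (!is.finite(s) || s < 1e-12)
    stop("cannot normalize a constant (zero-variance) volume")
  as_volume((v$data - mean(v$data)) / s, spacing = v$spacing,
            orientation = v$orientation)
}
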