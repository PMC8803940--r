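# Small-angle rigid resampling shared by the augmentation and the k-space
# motion simulator.

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

# Rotate a 3D array about its center plus an integer voxel offset.
# order = 1: trilinear (intensities); order = 0: nearest neighbour (labels).
# Voxels sampled from outside the input grid read `fill`.
rotate_array <- function(arr, angles_deg, center_offset = c(0, 0, 0),
                         order = 1, fill = 0) {
  if (all(angles_deg == 0)) return(arr)
  d <- dim(arr)
  ctr <- (d + 1) / 2 + center_offset
  R <- rotation_matrix(angles_deg)
  g <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                             k = seq_len(d[3])))
  src <- sweep(sweep(g, 2, ctr) %*% R, 2, ctr, `+`)
  out <- if (order == 0) {
    si <- round(src)
    ok <- si[, 1] >= 1 & si[, 1] <= d[1] & si[, 2] >= 1 & si[, 2] <= d[2] &
      si[, 3] >= 1 & si[, 3] <= d[3]
    val <- rep(fill, nrow(g))
    idx <- (si[ok, 3] - 1) * d[1] * d[2] + (si[ok, 2] - 1) * d[1] + si[ok, 1]
    val[ok] <- arr[idx]
    val
  } else {
    trilinear_sample(arr, src, fill)
  }
  array(out, d)
}

trilinear_sample <- function(arr, src, fill = 0) {
  d <- dim(arr)
  f <- floor(src)
  w <- src - f
  val <- rep(fill, nrow(src))
  ok <- f[, 1] >= 1 & f[, 1] <= d[1] - 1 & f[, 2] >= 1 & f[, 2] <= d[2] - 1 &
    f[, 3] >= 1 & f[, 3] <= d[3] - 1
  if (!any(ok)) return(val)
  f <- f[ok, , drop = FALSE]
  w <- w[ok, , drop = FALSE]
  base <- (f[, 3] - 1) * d[1] * d[2] + (f[, 2] - 1) * d[1] + f[, 1]
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    acc <- acc + wt * arr[base + dx + dy * d[1] + dz * d[1] * d[2]]
  }
  val[ok] <- acc
  val
}
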