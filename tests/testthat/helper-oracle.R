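# Independent brute-force oracles for the similarity metrics, written
# against voxel coordinate sets (not the package's array code paths).

oracle_counts <- function(a, b) {
  A <- which(a != 0)
  B <- which(b != 0)
  list(na = length(A), nb = length(B), ninter = length(intersect(A, B)),
       nunion = length(union(A, B)))
}

oracle_dsc <- function(a, b) {
  ct <- oracle_counts(a, b)
  if (ct$na + ct$nb == 0) return(NA_real_)
  2 * ct$ninter / (ct$na + ct$nb)
}

oracle_iou <- function(a, b) {
  ct <- oracle_counts(a, b)
  if (ct$nunion == 0) return(NA_real_)
  ct$ninter / ct$nunion
}

oracle_vd <- function(a, b) {
  vg <- sum(a != 0)
  if (vg == 0) return(NA_real_)
  abs(vg - sum(b != 0)) / vg
}

# boundary voxels by explicit per-voxel neighbour loops (6-connectivity,
# array borders count as outside)
oracle_boundary <- function(a) {
  a <- a != 0
  d <- dim(a)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!a[i, j, k]) next
    nb <- c(
      if (i > 1) a[i - 1, j, k] else FALSE,
      if (i < d[1]) a[i + 1, j, k] else FALSE,
      if (j > 1) a[i, j - 1, k] else FALSE,
      if (j < d[2]) a[i, j + 1, k] else FALSE,
      if (k > 1) a[i, j, k - 1] else FALSE,
      if (k < d[3]) a[i, j, k + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(i, j, k))
  }
  out
}

oracle_hausdorff <- function(a, b, spacing = c(1, 1, 1)) {
  if (sum(a != 0) == 0 || sum(b != 0) == 0) return(NA_real_)
  A <- sweep(oracle_boundary(a), 2, spacing, `*`)
  B <- sweep(oracle_boundary(b), 2, spacing, `*`)
  dmat <- sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# exact two-sided sign-flip enumeration of the Wilcoxon signed-rank test
oracle_wilcoxon_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# single connected component check (6-connectivity BFS)
oracle_is_connected <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  d <- dim(mask)
  key <- function(v) (v[, 3] - 1) * d[1] * d[2] + (v[, 2] - 1) * d[1] + v[, 1]
  all_keys <- key(idx)
  seen <- new.env()
  queue <- list(idx[1, ])
  assign(as.character(key(idx[1, , drop = FALSE])), TRUE, envir = seen)
  count <- 0
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    count <- count + 1
    for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      w <- v + step
      if (any(w < 1) || any(w > d)) next
      if (!mask[w[1], w[2], w[3]]) next
      kk <- as.character(key(matrix(w, 1)))
      if (!is.null(get0(kk, envir = seen))) next
      assign(kk, TRUE, envir = seen)
      queue[[length(queue) + 1]] <- w
    }
  }
  count == length(all_keys)
}

random_small_mask_pair <- function(seed) {
  set.seed(seed)
  d <- sample(4:10, 3, replace = TRUE)
  p <- runif(1, 0.1, 0.6)
  a <- array(runif(prod(d)) < p, d)
  b <- array(runif(prod(d)) < p, d)
  list(a = a, b = b, spacing = sample(c(1, 1, 2), 3, replace = TRUE))
}
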