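# Composite segmentation objective: focal loss + generalized Dice loss.

#' Segmentation loss configuration
#'
#' @param alpha focal weighting factor (default 4).
#' @param gamma focal focusing exponent (default 2, >= 0).
#' @param focal_weight,gdl_weight mixture weights of the two terms
#'   (default 1 each; not both zero).
#' @param eps stabilizer added to ground-truth class counts in the
#'   generalized Dice weights.
#' @return a \code{seg_loss_config} list.
#' @export
seg_loss_config <- function(alpha = 4, gamma = 2, focal_weight = 1,
                            gdl_weight = 1, eps = 1e-6) {
  stopifnot(gamma >= 0, focal_weight >= 0, gdl_weight >= 0,
            focal_weight + gdl_weight > 0, eps > 0)
  structure(list(alpha = alpha, gamma = gamma, focal_weight = focal_weight,
                 gdl_weight = gdl_weight, eps = eps),
            class = "seg_loss_config")
}

# coerce (probs, truth) into a (nvox x K) matrix and 1-based class indices
as_prob_matrix <- function(probs, truth, class_ids = NULL) {
  d <- dim(probs)
  stopifnot(length(d) == 4)
  tl <- if (is_label_mask(truth)) truth$labels else truth
  if (!all(dim(tl) == d[1:3]))
    stop("probability array and truth mask shapes differ")
  if (is.null(class_ids)) class_ids <- sort(unique(as.vector(tl)))
  if (length(class_ids) != d[4])
    stop("class dimension (", d[4], ") does not match class_ids (",
         length(class_ids), ")")
  ti <- match(as.vector(tl), class_ids)
  if (anyNA(ti)) stop("truth contains labels outside class_ids")
  list(pm = matrix(probs, nrow = prod(d[1:3]), ncol = d[4]), ti = ti,
       class_ids = class_ids)
}

#' Focal loss
#'
#' Mean over voxels of \code{-alpha * (1 - p_t)^gamma * log(p_t)}, where
#' \code{p_t} is the predicted probability of the true class; with
#' \code{alpha = 1, gamma = 0} this is exactly the mean cross-entropy.
#'
#' @param probs 4D array \code{(i, j, k, class)} of per-voxel class
#'   probabilities, normalized per voxel.
#' @param truth a \code{label_mask} (or integer array) of the same spatial
#'   shape.
#' @param alpha,gamma focal parameters.
#' @param class_ids label id of each class channel; defaults to the sorted
#'   labels present in \code{truth}.
#' @return scalar loss.
#' @export
focal_loss <- function(probs, truth, alpha = 4, gamma = 2,
                       class_ids = NULL) {
  z <- as_prob_matrix(probs, truth, class_ids)
  pt <- pmax(z$pm[cbind(seq_along(z$ti), z$ti)], 1e-12)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' Generalized Dice loss
#'
#' \code{1 - 2 * sum_l w_l sum_v p_lv y_lv / sum_l w_l sum_v (p_lv + y_lv)}
#' with class weights \code{w_l = 1 / (n_l + eps)^2}, \code{n_l} the
#' ground-truth voxel count of class \code{l}; the inverse-square-count
#' weighting balances classes of very different volumetric size.
#'
#' @inheritParams focal_loss
#' @param eps stabilizer for classes absent from the truth.
#' @return scalar loss in [0, 1] (up to the eps contribution).
#' @export
gdl <- function(probs, truth, eps = 1e-6, class_ids = NULL) {
  z <- as_prob_matrix(probs, truth, class_ids)
  K <- ncol(z$pm)
  n_l <- tabulate(z$ti, nbins = K)
  w <- gdl_weights(n_l, eps)
  inter <- vapply(seq_len(K), function(l) sum(z$pm[z$ti == l, l]),
                  numeric(1))
  psum <- colSums(z$pm)
  1 - 2 * sum(w * inter) / sum(w * (psum + n_l))
}

#' Composite segmentation loss
#'
#' \code{focal_weight * focal_loss + gdl_weight * gdl}.
#'
#' @inheritParams focal_loss
#' @param cfg a \code{\link{seg_loss_config}}.
#' @return scalar loss.
#' @export
seg_loss <- function(probs, truth, cfg = seg_loss_config(),
                     class_ids = NULL) {
  cfg$focal_weight * focal_loss(probs, truth, cfg$alpha, cfg$gamma,
                                class_ids) +
    cfg$gdl_weight * gdl(probs, truth, cfg$eps, class_ids)
}

# Inverse-square-count class weights.  Classes absent from the truth would
# get a weight of 1/eps^2, which dwarfs every present class and makes the
# loss gradient almost entirely about suppressing rare labels wherever they
# are absent; their weight is therefore capped at the largest present-class
# weight (a standard stabilization of generalized Dice implementations).
gdl_weights <- function(n_l, eps) {
  w <- 1 / (n_l + eps)^2
  if (any(n_l > 0) && any(n_l == 0))
    w[n_l == 0] <- max(w[n_l > 0])
  w
}

# ---- internal: loss value + gradient wrt logits (matrix form) -------------
# pm: softmax probabilities (nvox x K); ti: true class index per voxel.
seg_loss_grad_matrix <- function(pm, ti, cfg) {
  nvox <- nrow(pm)
  K <- ncol(pm)
  idx <- cbind(seq_len(nvox), ti)
  pt <- pmax(pm[idx], 1e-12)

  # focal value and d(loss)/d(p_t)
  om <- 1 - pt
  fval <- mean(-cfg$alpha * om^cfg$gamma * log(pt))
  dfdpt <- -cfg$alpha *
    (om^cfg$gamma / pt - (if (cfg$gamma > 0)
      cfg$gamma * om^(cfg$gamma - 1) * log(pt) else 0)) / nvox

  # GDL value and d(loss)/d(p_lv)
  n_l <- tabulate(ti, nbins = K)
  w <- gdl_weights(n_l, cfg$eps)
  inter <- vapply(seq_len(K), function(l) sum(pm[ti == l, l]), numeric(1))
  psum <- colSums(pm)
  num <- sum(w * inter)
  den <- sum(w * (psum + n_l))
  gval <- 1 - 2 * num / den
  # dG/dp_lv = -2 * (w_l y_lv * den - num * w_l) / den^2
  gmat <- matrix(rep(2 * num * w / den^2, each = nvox), nvox, K)
  gmat[idx] <- gmat[idx] - 2 * w[ti] / den

  # chain through softmax: dL/dz_c = p_c * (g_c - sum_l g_l p_l)
  gtot <- cfg$gdl_weight * gmat
  # focal depends only on p_t
  gfoc <- matrix(0, nvox, K)
  gfoc[idx] <- cfg$focal_weight * dfdpt
  g <- gtot + gfoc
  dz <- pm * (g - rowSums(g * pm))
  list(value = cfg$focal_weight * fval + cfg$gdl_weight * gval, dlogits = dz)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
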