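#' Training configuration for the cropping network
#'
#' Defaults follow the published recipe: Adam with an exponentially
#' decaying learning rate \code{lr0 * r^(epoch/s)}, L1L2 weight penalties
#' of 0.01 each on every convolutional layer, mini-batches of 8 and early
#' stopping with a patience of 20 epochs.  \code{lr0} is the printed value
#' \code{10e-4} taken literally (= 1e-3); pass \code{lr0 = 1e-4} for the
#' other reading.
#'
#' @param lr0 initial learning rate.
#' @param r decay ratio per \code{s} epochs, in (0, 1].
#' @param s decay step in epochs.
#' @param l1,l2 L1 and L2 penalty weights on convolution kernels.
#' @param batch_size mini-batch size.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param max_epochs hard cap on training length.
#' @return a \code{crop_train_config} list.
#' @export
crop_train_config <- function(lr0 = 10e-4, r = 0.92, s = 10,
                              l1 = 0.01, l2 = 0.01, batch_size = 8,
                              patience = 20, max_epochs = 100) {
  stopifnot(lr0 > 0, r > 0, r <= 1, s > 0, l1 >= 0, l2 >= 0,
            batch_size >= 1, patience >= 1, max_epochs >= 1)
  structure(list(lr0 = lr0, r = r, s = s, l1 = l1, l2 = l2,
                 batch_size = batch_size, patience = patience,
                 max_epochs = max_epochs), class = "crop_train_config")
}

#' Exponentially decaying learning-rate schedule
#'
#' \code{lr0 * r^(epoch / s)}: equal to \code{lr0} at epoch 0 and decayed
#' by the factor \code{r} every \code{s} epochs.
#'
#' @param epoch epoch counter, >= 0.
#' @param cfg a \code{\link{crop_train_config}}.
#' @return the learning rate at \code{epoch}.
#' @export
#' @examples
#' cfg <- crop_train_config()
#' lr_schedule(0, cfg)                      # lr0
#' lr_schedule(cfg$s, cfg) / lr_schedule(0, cfg)  # r = 0.92
lr_schedule <- function(epoch, cfg = crop_train_config()) {
  stopifnot(all(epoch >= 0))
  cfg$lr0 * cfg$r^(epoch / cfg$s)
}

#' Build the bounding-box regression network
#'
#' A convolutional regressor that maps the downsampled conformed volume to
#' the 6-vector \code{(i0, j0, k0, di, dj, dk)} of the tight brain box (in
#' downsampled voxel units).  Structure: 16 convolutional layers (3^3
#' kernels, SAME padding, Swish activations, L1L2-penalized weights,
#' dimension reduction only by strided convolution — no pooling layers),
#' followed by 2 hidden dense layers with Swish and a linear 6-unit output.
#' Biases start at zero, weights He-initialized.
#'
#' @param geometry a \code{\link{pipeline_geometry}}; the input extent is
#'   \code{geometry$crop_input_shape}.
#' @param channels output channels of the 16 convolutional layers.
#' @param strides stride of each convolutional layer (exactly four stride-2
#'   reductions by default).
#' @param dense_units sizes of the two hidden dense layers.
#' @param layer_types layer kinds; anything other than \code{"conv"} (for
#'   instance a pooling layer) is rejected.
#' @param seed initialization seed.
#' @return a \code{cropnet} model object.
#' @export
build_cropnet <- function(geometry,
                          channels = c(4, 4, 4, 8, 8, 8, 8, 8, 8,
                                       16, 16, 16, 16, 16, 16, 16),
                          strides = c(2, 1, 1, 2, 1, 1, 2, 1, 1,
                                      2, 1, 1, 1, 1, 1, 1),
                          dense_units = c(32, 16),
                          layer_types = rep("conv", 16), seed = 1) {
  if (any(layer_types != "conv"))
    stop("only convolutional layers are allowed; pooling layers are rejected")
  stopifnot(length(channels) == 16, length(strides) == 16,
            length(dense_units) == 2)
  in_shape <- geometry$crop_input_shape
  sp <- in_shape
  arch <- vector("list", 16)
  cin <- 1L
  for (i in 1:16) {
    arch[[i]] <- list(cin = cin, cout = channels[i], stride = strides[i])
    sp <- (sp + 2 - 3) %/% strides[i] + 1
    cin <- channels[i]
  }
  flat <- prod(sp) * cin
  model <- structure(list(geometry = geometry, arch = arch,
                          conv_out_shape = c(sp, cin), flat = flat,
                          dense_units = dense_units,
                          n_pooling = 0L, n_conv = 16L, n_dense = 3L,
                          seed = seed),
                     class = "cropnet")
  model$params <- with_seed(seed, {
    p <- list()
    for (i in 1:16) {
      p[[sprintf("conv%02d.W", i)]] <-
        init_conv_w(c(3, 3, 3), arch[[i]]$cin, arch[[i]]$cout)
      p[[sprintf("conv%02d.b", i)]] <- rep(0, arch[[i]]$cout)
    }
    p[["fc1.W"]] <- init_dense_w(flat, dense_units[1])
    p[["fc1.b"]] <- rep(0, dense_units[1])
    p[["fc2.W"]] <- init_dense_w(dense_units[1], dense_units[2])
    p[["fc2.b"]] <- rep(0, dense_units[2])
    p[["out.W"]] <- init_dense_w(dense_units[2], 6) * 0.1
    p[["out.b"]] <- rep(0, 6)
    p
  })
  model
}

cropnet_forward <- function(model, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  p <- model$params
  cache <- list(inputs = list(), pre = list())
  h <- x
  for (i in 1:16) {
    a <- model$arch[[i]]
    if (keep_cache) cache$inputs[[i]] <- h
    z <- conv3d_forward(h, p[[sprintf("conv%02d.W", i)]],
                        p[[sprintf("conv%02d.b", i)]],
                        c(3, 3, 3), rep(a$stride, 3), c(1, 1, 1))
    if (keep_cache) cache$pre[[i]] <- z
    h <- swish(z)
  }
  flat <- as.numeric(h)
  z1 <- drop(flat %*% p$fc1.W) + p$fc1.b
  h1 <- swish(z1)
  z2 <- drop(h1 %*% p$fc2.W) + p$fc2.b
  h2 <- swish(z2)
  out <- drop(h2 %*% p$out.W) + p$out.b
  if (!keep_cache) return(out)
  cache$flat <- flat; cache$z1 <- z1; cache$h1 <- h1
  cache$z2 <- z2; cache$h2 <- h2; cache$conv_dim <- dim(h)
  list(out = out, cache = cache)
}

cropnet_backward <- function(model, cache, dout) {
  p <- model$params
  g <- list()
  g[["out.W"]] <- outer(cache$h2, dout)
  g[["out.b"]] <- dout
  dh2 <- drop(p$out.W %*% dout)
  dz2 <- dh2 * swish_grad(cache$z2)
  g[["fc2.W"]] <- outer(cache$h1, dz2)
  g[["fc2.b"]] <- dz2
  dh1 <- drop(p$fc2.W %*% dz2)
  dz1 <- dh1 * swish_grad(cache$z1)
  g[["fc1.W"]] <- outer(cache$flat, dz1)
  g[["fc1.b"]] <- dz1
  dh <- array(drop(p$fc1.W %*% dz1), cache$conv_dim)
  for (i in 16:1) {
    a <- model$arch[[i]]
    dz <- dh * swish_grad(cache$pre[[i]])
    bw <- conv3d_backward(cache$inputs[[i]], p[[sprintf("conv%02d.W", i)]],
                          dz, c(3, 3, 3), rep(a$stride, 3), c(1, 1, 1),
                          need_dx = (i > 1))
    g[[sprintf("conv%02d.W", i)]] <- bw$dw
    g[[sprintf("conv%02d.b", i)]] <- bw$db
    if (i > 1) dh <- bw$dx
  }
  g
}

# L1L2 penalty on convolution kernels: value and gradient contribution
cropnet_penalty <- function(model, cfg) {
  val <- 0
  for (i in 1:16) {
    w <- model$params[[sprintf("conv%02d.W", i)]]
    val <- val + cfg$l1 * sum(abs(w)) + cfg$l2 * sum(w^2)
  }
  val
}

#' Train the cropping network
#'
#' Minimizes the mean squared error between the predicted and target
#' 6-vectors (plus the L1L2 kernel penalties) with Adam, the learning rate
#' following \code{\link{lr_schedule}} per epoch, and early stopping on the
#' validation MSE.  The best-validation weights are returned.
#'
#' @param pairs training list; each element has \code{volume} (a conformed,
#'   intensity-normalized \code{brain_volume}) and \code{box} (the tight
#'   \code{\link{bounding_box}} from \code{\link{bbox_target}}).
#' @param cfg a \code{\link{crop_train_config}}.
#' @param val_pairs validation list of the same structure (>= 1 pair).
#' @param geometry a \code{\link{pipeline_geometry}}.
#' @param seed seed for initialization and shuffling.
#' @param verbose print per-epoch losses.
#' @return a trained \code{cropnet}; \code{$history} holds per-epoch
#'   training/validation losses.
#' @export
train_cropnet <- function(pairs, cfg = crop_train_config(), val_pairs,
                          geometry, seed = 1, verbose = FALSE) {
  if (length(pairs) < 2) stop("need at least 2 training pairs")
  if (missing(val_pairs) || length(val_pairs) < 1)
    stop("need at least 1 validation pair")
  prep <- function(p) {
    x <- downsample_volume(p$volume, geometry$downsample)$data
    dim(x) <- c(dim(x), 1L)
    y <- c(p$box$start, p$box$lengths) * geometry$downsample
    list(x = x, y = y)
  }
  tr <- lapply(pairs, prep)
  va <- lapply(val_pairs, prep)

  model <- build_cropnet(geometry, seed = derive_seed(seed, "init"))
  opt <- optimizer_init("adam", model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0)
  wait <- 0
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_schedule(epoch - 1, cfg)
    ord <- with_seed(derive_seed(seed, "shuffle", epoch),
                     sample(length(tr)))
    ep_loss <- 0
    nb <- 0
    for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
      bidx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
      grads <- NULL
      bl <- 0
      for (i in bidx) {
        fw <- cropnet_forward(model, tr[[i]]$x, keep_cache = TRUE)
        err <- fw$out - tr[[i]]$y
        bl <- bl + mean(err^2)
        grads <- grads_add(grads,
                           cropnet_backward(model, fw$cache, 2 * err / 6))
      }
      grads <- grads_scale(grads, 1 / length(bidx))
      for (i in 1:16) {
        nm <- sprintf("conv%02d.W", i)
        w <- model$params[[nm]]
        grads[[nm]] <- grads[[nm]] + cfg$l1 * sign(w) + 2 * cfg$l2 * w
      }
      st <- optimizer_step(opt, model$params, grads, lr)
      opt <- st$opt
      model$params <- st$params
      ep_loss <- ep_loss + bl / length(bidx)
      nb <- nb + 1
    }
    val_loss <- mean(vapply(va, function(v) {
      mean((cropnet_forward(model, v$x) - v$y)^2)
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, train = ep_loss / nb,
                                   val = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.3f  val %.3f",
                      epoch, lr, ep_loss / nb, val_loss))
    if (val_loss < best$loss - 1e-10) {
      best <- list(loss = val_loss, params = model$params, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

#' Predict the finalized crop box for a volume
#'
#' @param model a trained \code{cropnet}.
#' @param volume a conformed, intensity-normalized \code{brain_volume}.
#' @param finalize return the fixed-size \code{\link{finalize_bbox}} box
#'   (default) or the raw 6-vector in downsampled coordinates.
#' @return a \code{\link{bounding_box}}, or the raw prediction.
#' @export
predict_bbox <- function(model, volume, finalize = TRUE) {
  stopifnot(inherits(model, "cropnet"), is_volume(volume))
  x <- downsample_volume(volume, model$geometry$downsample)$data
  dim(x) <- c(dim(x), 1L)
  pred <- cropnet_forward(model, x)
  if (!finalize) return(pred)
  finalize_bbox(pred, model$geometry, vol_shape = dim(volume$data))
}
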