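#' Build the subvolume segmentation network
#'
#' An encoder-decoder volumetric network in the U-Net family: two
#' convolutional blocks at full resolution, a strided-convolution
#' downsampling stage (no pooling layers), a bottleneck block, nearest
#' -neighbour upsampling followed by a convolutional block, a concatenating
#' skip connection from the encoder, a decoder block, and a linear 1^3
#' output convolution.  Every convolution uses SAME padding and is followed
#' by batch normalization and Swish, so the spatial output shape equals the
#' input subvolume shape.
#'
#' @param geometry a \code{\link{pipeline_geometry}}; the input extent is
#'   \code{geometry$sub_shape} (must be even per axis).
#' @param n_classes number of output classes.
#' @param channels encoder/bottleneck widths \code{c(C1, C2)}.
#' @param layer_types layer kinds; anything other than \code{"conv"} or
#'   \code{"bn"} (for instance pooling) is rejected.
#' @param seed initialization seed.
#' @return a \code{segnet} model object.
#' @export
build_segnet <- function(geometry, n_classes, channels = c(6, 12),
                         layer_types = c(rep(c("conv", "bn"), 6), "conv"),
                         seed = 1) {
  if (!all(layer_types %in% c("conv", "bn")))
    stop("only convolutional and batch normalization layers are allowed; ",
         "pooling layers are rejected")
  stopifnot(length(channels) == 2, n_classes >= 2)
  ss <- geometry$sub_shape
  if (any(ss %% 2 != 0)) stop("sub_shape must be even along every axis")
  C1 <- channels[1]; C2 <- channels[2]
  blocks <- list(e1a = c(1, C1, 1), e1b = c(C1, C1, 1),
                 down = c(C1, C2, 2), bott = c(C2, C2, 1),
                 upc = c(C2, C1, 1), dec = c(2 * C1, C1, 1))
  model <- structure(list(geometry = geometry, n_classes = n_classes,
                          channels = channels, blocks = blocks,
                          n_pooling = 0L, n_skip = 1L,
                          n_conv = length(blocks) + 1L,
                          n_bn = length(blocks), seed = seed),
                     class = "segnet")
  model$params <- with_seed(seed, {
    p <- list()
    for (nm in names(blocks)) {
      b <- blocks[[nm]]
      p[[paste0(nm, ".W")]] <- init_conv_w(c(3, 3, 3), b[1], b[2])
      p[[paste0(nm, ".b")]] <- rep(0, b[2])
      p[[paste0(nm, ".gamma")]] <- rep(1, b[2])
      p[[paste0(nm, ".beta")]] <- rep(0, b[2])
    }
    p[["out.W"]] <- init_conv_w(c(1, 1, 1), C1, n_classes)
    p[["out.b"]] <- rep(0, n_classes)
    p
  })
  model$bn <- lapply(blocks, function(b) bn_init(b[2]))
  model
}

# conv + BN + swish block; returns output, cache and updated bn state
seg_block_forward <- function(model, nm, x, stride, training,
                              keep_cols = FALSE) {
  p <- model$params
  z <- conv3d_forward(x, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]],
                      c(3, 3, 3), rep(stride, 3), c(1, 1, 1),
                      return_cols = keep_cols)
  cols <- NULL
  if (keep_cols) { cols <- z$cols; z <- z$y }
  bn <- bn_forward(z, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                   model$bn[[nm]], training)
  h <- swish(bn$y)
  list(h = h, cache = list(x = x, zbn = bn$y, bncache = bn$cache,
                           stride = stride, cols = cols), state = bn$state)
}

seg_block_backward <- function(model, nm, cache, dh, need_dx = TRUE) {
  p <- model$params
  dzbn <- dh * swish_grad(cache$zbn)
  bnb <- bn_backward(dzbn, p[[paste0(nm, ".gamma")]], cache$bncache)
  cb <- conv3d_backward(cache$x, p[[paste0(nm, ".W")]], bnb$dx,
                        c(3, 3, 3), rep(cache$stride, 3), c(1, 1, 1),
                        need_dx = need_dx, cols = cache$cols)
  g <- list()
  g[[paste0(nm, ".W")]] <- cb$dw
  g[[paste0(nm, ".b")]] <- cb$db
  g[[paste0(nm, ".gamma")]] <- bnb$dgamma
  g[[paste0(nm, ".beta")]] <- bnb$dbeta
  list(grads = g, dx = if (need_dx) cb$dx else NULL)
}

# forward pass over one subvolume; x: 3D array (or 4D with one channel)
segnet_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  kc <- keep_cache
  cc <- list()
  f <- seg_block_forward(model, "e1a", x, 1, training, kc)
  model$bn$e1a <- f$state; cc$e1a <- f$cache
  f2 <- seg_block_forward(model, "e1b", f$h, 1, training, kc)
  model$bn$e1b <- f2$state; cc$e1b <- f2$cache
  h_e1b <- f2$h
  f3 <- seg_block_forward(model, "down", h_e1b, 2, training, kc)
  model$bn$down <- f3$state; cc$down <- f3$cache
  f4 <- seg_block_forward(model, "bott", f3$h, 1, training, kc)
  model$bn$bott <- f4$state; cc$bott <- f4$cache
  up <- upsample2(f4$h)
  f5 <- seg_block_forward(model, "upc", up, 1, training, kc)
  model$bn$upc <- f5$state; cc$upc <- f5$cache
  d <- dim(f5$h)
  cat_h <- array(0, c(d[1:3], d[4] + dim(h_e1b)[4]))
  cat_h[, , , seq_len(d[4])] <- f5$h
  cat_h[, , , d[4] + seq_len(dim(h_e1b)[4])] <- h_e1b
  f6 <- seg_block_forward(model, "dec", cat_h, 1, training, kc)
  model$bn$dec <- f6$state; cc$dec <- f6$cache
  logits <- conv3d_forward(f6$h, model$params$out.W, model$params$out.b,
                           c(1, 1, 1), c(1, 1, 1), c(0, 0, 0))
  out <- list(logits = logits, bn = model$bn)
  if (keep_cache) {
    cc$out_x <- f6$h
    cc$c1 <- dim(f5$h)[4]
    out$cache <- cc
  }
  out
}

segnet_backward <- function(model, cache, dlogits) {
  cb <- conv3d_backward(cache$out_x, model$params$out.W, dlogits,
                        c(1, 1, 1), c(1, 1, 1), c(0, 0, 0))
  g <- list(out.W = cb$dw, out.b = cb$db)
  b6 <- seg_block_backward(model, "dec", cache$dec, cb$dx)
  g <- c(g, b6$grads)
  C1 <- cache$c1
  d_upc <- b6$dx[, , , seq_len(C1), drop = FALSE]
  d_skip <- b6$dx[, , , C1 + seq_len(dim(b6$dx)[4] - C1), drop = FALSE]
  b5 <- seg_block_backward(model, "upc", cache$upc, d_upc)
  g <- c(g, b5$grads)
  d_bott <- upsample2_backward(b5$dx)
  b4 <- seg_block_backward(model, "bott", cache$bott, d_bott)
  g <- c(g, b4$grads)
  b3 <- seg_block_backward(model, "down", cache$down, b4$dx)
  g <- c(g, b3$grads)
  b2 <- seg_block_backward(model, "e1b", cache$e1b, b3$dx + d_skip)
  g <- c(g, b2$grads)
  b1 <- seg_block_backward(model, "e1a", cache$e1a, b2$dx, need_dx = FALSE)
  c(g, b1$grads)
}

#' Training configuration for the segmentation network
#'
#' Defaults follow the published recipe: RMSprop, mini-batches of 2
#' subvolumes, early stopping with a patience of 25 epochs, the focal +
#' generalized Dice composite objective, and online rotation augmentation.
#' The RMSprop learning rate is an implementation choice (3e-3, from
#' pilot convergence runs on desk-scale phantoms).
#'
#' @param lr RMSprop learning rate.
#' @param batch_size subvolumes per optimization step.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs hard cap on training length.
#' @param loss a \code{\link{seg_loss_config}}.
#' @param augment an \code{\link{augment_config}}.
#' @param subvols_per_pair if set, randomly subsample this many grid
#'   subvolumes per volume per epoch instead of all of them.
#' @return a \code{seg_train_config} list.
#' @export
seg_train_config <- function(lr = 3e-3, batch_size = 2, patience = 25,
                             max_epochs = 8, loss = seg_loss_config(),
                             augment = augment_config(),
                             subvols_per_pair = NULL) {
  stopifnot(lr > 0, batch_size >= 1, patience >= 1, max_epochs >= 1)
  structure(list(lr = lr, batch_size = batch_size, patience = patience,
                 max_epochs = max_epochs, loss = loss, augment = augment,
                 subvols_per_pair = subvols_per_pair),
            class = "seg_train_config")
}

#' Train the segmentation network
#'
#' Iterates over the overlapping grid subvolumes of the (optionally
#' rotation-augmented) cropped training pairs, optimizing the focal +
#' generalized Dice objective with RMSprop; early stopping monitors the
#' validation loss over all subvolumes of the validation pairs and the
#' best-validation weights are returned.
#'
#' @param pairs training list; each element has \code{volume} (cropped,
#'   intensity-normalized \code{brain_volume}) and \code{mask} (the
#'   matching cropped \code{label_mask}).
#' @param cfg a \code{\link{seg_train_config}}.
#' @param val_pairs validation list of the same structure (>= 1 pair).
#' @param geometry a \code{\link{pipeline_geometry}}.
#' @param seed seed for initialization, augmentation and shuffling.
#' @param verbose print per-epoch losses.
#' @return a trained \code{segnet} with \code{$class_ids} (label id per
#'   output channel), \code{$scheme} and \code{$history}.
#' @export
train_segnet <- function(pairs, cfg = seg_train_config(), val_pairs,
                         geometry, seed = 1, verbose = FALSE) {
  if (length(pairs) < 2) stop("need at least 2 training pairs")
  if (missing(val_pairs) || length(val_pairs) < 1)
    stop("need at least 1 validation pair")
  scheme <- pairs[[1]]$mask$scheme
  class_ids <- sort(unique(unlist(lapply(pairs, function(p)
    unique(as.vector(p$mask$labels))))))
  K <- length(class_ids)
  grid <- subvolume_grid(geometry$crop_lengths, geometry$sub_shape,
                         geometry$step)

  model <- build_segnet(geometry, K, seed = derive_seed(seed, "init"))
  model$class_ids <- class_ids
  model$scheme <- scheme
  opt <- optimizer_init("rmsprop", model$params)

  val_subs <- lapply(val_pairs, function(p) {
    lapply(seq_len(nrow(grid$starts)), function(m) {
      st <- grid$starts[m, ]
      list(x = extract_subvolume(p$volume$data, st, grid$sub_shape),
           ti = match(as.vector(extract_subvolume(p$mask$labels, st,
                                                  grid$sub_shape)),
                      class_ids))
    })
  })
  val_loss_fun <- function() {
    tot <- 0; n <- 0
    for (vs in val_subs) for (s in vs) {
      lg <- segnet_forward(model, s$x, training = FALSE)$logits
      pm <- softmax_rows(matrix(lg, ncol = K))
      tot <- tot + seg_loss_grad_matrix(pm, s$ti, cfg$loss)$value
      n <- n + 1
    }
    tot / n
  }

  best <- list(loss = Inf, params = model$params, bn = model$bn, epoch = 0)
  wait <- 0
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())

  for (epoch in seq_len(cfg$max_epochs)) {
    # augmented copies for this epoch
    aug <- lapply(seq_along(pairs), function(i)
      augment_pair(pairs[[i]]$volume, pairs[[i]]$mask, cfg$augment,
                   seed = derive_seed(seed, "aug", epoch, i)))
    combos <- expand.grid(pair = seq_along(pairs),
                          sub = seq_len(nrow(grid$starts)))
    if (!is.null(cfg$subvols_per_pair)) {
      keep <- with_seed(derive_seed(seed, "subsel", epoch), {
        unlist(lapply(seq_along(pairs), function(i)
          which(combos$pair == i)[sample.int(nrow(grid$starts),
                                             cfg$subvols_per_pair)]))
      })
      combos <- combos[keep, ]
    }
    ord <- with_seed(derive_seed(seed, "shuffle", epoch),
                     sample(nrow(combos)))
    combos <- combos[ord, ]

    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, nrow(combos), by = cfg$batch_size)) {
      rows <- combos[b0:min(b0 + cfg$batch_size - 1, nrow(combos)), ]
      grads <- NULL
      bl <- 0
      for (ri in seq_len(nrow(rows))) {
        i <- rows$pair[ri]; m <- rows$sub[ri]
        st <- grid$starts[m, ]
        x <- extract_subvolume(aug[[i]]$volume$data, st, grid$sub_shape)
        ti <- match(as.vector(extract_subvolume(aug[[i]]$mask$labels, st,
                                                grid$sub_shape)), class_ids)
        fw <- segnet_forward(model, x, training = TRUE, keep_cache = TRUE)
        model$bn <- fw$bn
        pm <- softmax_rows(matrix(fw$logits, ncol = K))
        lg <- seg_loss_grad_matrix(pm, ti, cfg$loss)
        bl <- bl + lg$value
        dlog <- array(lg$dlogits, dim(fw$logits))
        grads <- grads_add(grads, segnet_backward(model, fw$cache, dlog))
      }
      grads <- grads_scale(grads, 1 / nrow(rows))
      st2 <- optimizer_step(opt, model$params, grads, cfg$lr)
      opt <- st2$opt
      model$params <- st2$params
      ep_loss <- ep_loss + bl / nrow(rows)
      nb <- nb + 1
    }
    vl <- val_loss_fun()
    hist <- rbind(hist, data.frame(epoch = epoch, train = ep_loss / nb,
                                   val = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / nb, vl))
    if (vl < best$loss - 1e-10) {
      best <- list(loss = vl, params = model$params, bn = model$bn,
                   epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$bn <- best$bn
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

# per-subvolume scorer for the different model kinds
subvolume_scorer <- function(seg_model) {
  if (is.function(seg_model)) return(seg_model)
  if (inherits(seg_model, "segnet"))
    return(function(x) segnet_forward(seg_model, x)$logits)
  if (inherits(seg_model, "nearest_mean_model")) {
    means <- seg_model$means
    return(function(x) {
      d <- dim(x)
      sc <- vapply(means, function(mu) -abs(as.vector(x) - mu),
                   numeric(prod(d)))
      array(sc, c(d, length(means)))
    })
  }
  stop("unsupported segmentation model")
}

#' Segment a cropped volume
#'
#' Scores every subvolume of the overlap grid, merges the scores with
#' \code{\link{merge_predictions}} and takes the voxelwise argmax.
#'
#' @param seg_model a trained \code{segnet} (or a function mapping a
#'   subvolume array to a 4D score array, or a
#'   \code{\link{nearest_mean_model}}).
#' @param cropped a cropped, intensity-normalized \code{brain_volume}.
#' @param geometry a \code{\link{pipeline_geometry}} (taken from the model
#'   if absent).
#' @param class_ids label id per score channel (taken from the model if
#'   absent).
#' @return list with \code{labels} (3D integer array over the crop
#'   extent), \code{scores} (the merged \code{score_volume}).
#' @export
predict_cropped <- function(seg_model, cropped, geometry = NULL,
                            class_ids = NULL) {
  stopifnot(is_volume(cropped))
  geometry <- geometry %||% seg_model$geometry
  class_ids <- class_ids %||% seg_model$class_ids
  grid <- subvolume_grid(dim(cropped$data), geometry$sub_shape,
                         geometry$step)
  scorer <- subvolume_scorer(seg_model)
  subs <- lapply(seq_len(nrow(grid$starts)), function(m)
    scorer(extract_subvolume(cropped$data, grid$starts[m, ],
                             grid$sub_shape)))
  sv <- merge_predictions(subs, grid)
  idx <- score_argmax(sv)
  list(labels = array(as.integer(class_ids[idx]), dim(idx)), scores = sv)
}

#' End-to-end segmentation of a conformed volume
#'
#' Conform, normalize, localize the fixed-size crop box, segment the
#' cropped block by overlapping subvolumes, merge, and pad the decision
#' back to the full extent with the Unknown label.
#'
#' @param volume an input \code{brain_volume} (any spacing; conformed
#'   internally to the geometry's grid).
#' @param crop_model a trained \code{cropnet}, or a fixed
#'   \code{\link{bounding_box}} (e.g. for oracle tests).
#' @param seg_model a trained \code{segnet}, scorer function or
#'   \code{\link{nearest_mean_model}}.
#' @param geometry a \code{\link{pipeline_geometry}}; defaults to the crop
#'   model's.
#' @param scheme output \code{\link{label_scheme}}; defaults to the seg
#'   model's.
#' @param class_ids label id per score channel if \code{seg_model} is a
#'   bare function.
#' @return the predicted \code{label_mask} over the full conformed extent;
#'   voxels outside the crop box carry the Unknown label.
#' @export
predict_mask <- function(volume, crop_model, seg_model, geometry = NULL,
                         scheme = NULL, class_ids = NULL) {
  geometry <- geometry %||% crop_model$geometry %||% seg_model$geometry
  scheme <- scheme %||% seg_model$scheme
  if (is.null(scheme)) stop("a label scheme is required")
  conf <- conform(volume, shape = geometry$input_shape,
                  spacing = geometry$spacing_mm)
  conf <- normalize_intensity(conf)
  box <- if (inherits(crop_model, "bounding_box")) crop_model
         else predict_bbox(crop_model, conf)
  cropped <- crop(conf, box)
  pr <- predict_cropped(seg_model, cropped, geometry = geometry,
                        class_ids = class_ids)
  cropped_mask <- as_label_mask(pr$labels, scheme, spacing = conf$spacing,
                                orientation = conf$orientation)
  uncrop(cropped_mask, box, geometry$input_shape,
         fill = unknown_id(scheme))
}

#' Nearest-tissue-mean baseline segmenter
#'
#' A deliberately simple comparison method for the evaluation framework:
#' each class gets the mean normalized intensity of its training voxels,
#' and a voxel is scored by the negative absolute distance to each class
#' mean.  It shares the subvolume/merge inference path of the main model.
#'
#' @param pairs cropped training pairs as in \code{\link{train_segnet}}.
#' @param geometry a \code{\link{pipeline_geometry}}.
#' @return a \code{nearest_mean_model}.
#' @export
nearest_mean_model <- function(pairs, geometry) {
  scheme <- pairs[[1]]$mask$scheme
  class_ids <- sort(unique(unlist(lapply(pairs, function(p)
    unique(as.vector(p$mask$labels))))))
  sums <- numeric(length(class_ids))
  cnts <- numeric(length(class_ids))
  for (p in pairs) {
    ti <- match(as.vector(p$mask$labels), class_ids)
    x <- as.vector(p$volume$data)
    for (l in seq_along(class_ids)) {
      sel <- ti == l
      sums[l] <- sums[l] + sum(x[sel])
      cnts[l] <- cnts[l] + sum(sel)
    }
  }
  structure(list(means = as.list(sums / pmax(cnts, 1)),
                 class_ids = class_ids, scheme = scheme,
                 geometry = geometry), class = "nearest_mean_model")
}
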