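#' Swish activation
#'
#' The smooth self-gated activation \code{x * sigmoid(x)} used by the hidden
#' layers of the cropping and segmentation networks.
#'
#' @param x numeric vector or array.
#' @return numeric of the same shape, \code{x * sigmoid(x)}.
#' @export
#' @examples
#' swish(0)      # 0
#' swish(1)      # 0.7311
swish <- function(x) x / (1 + exp(-x))

# derivative of swish wrt its input
swish_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

# ---- low-level layer primitives -------------------------------------------
# Volumes are R arrays with dim c(d1, d2, d3, channels).  Weights of a 3D
# convolution are stored as a matrix with rows indexed by the column-major
# flattening of (k1, k2, k3, cin) and one column per output channel.

conv3d_forward <- function(x, w, b, kdim, stride, pad, return_cols = FALSE) {
  out <- .cpp_conv3d_forward(x, as.integer(dim(x)), w, b,
                             as.integer(kdim), as.integer(stride),
                             as.integer(pad), return_cols)
  if (return_cols) out else out$y
}

# `cols` may carry the im2col matrix cached by the forward pass
conv3d_backward <- function(x, w, dy, kdim, stride, pad, need_dx = TRUE,
                            cols = NULL) {
  .cpp_conv3d_backward(x, as.integer(dim(x)), w, dy,
                       as.integer(kdim), as.integer(stride), as.integer(pad),
                       need_dx, cols)
}

# He-style initialization for a conv kernel; returns the weight matrix.
init_conv_w <- function(kdim, cin, cout, rng_sd = NULL) {
  fan_in <- prod(kdim) * cin
  sd <- if (is.null(rng_sd)) sqrt(2 / fan_in) else rng_sd
  matrix(stats::rnorm(fan_in * cout, sd = sd), nrow = fan_in, ncol = cout)
}

init_dense_w <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nrow = nin, ncol = nout)
}

# Nearest-neighbour x2 upsampling along the three spatial axes, and its
# adjoint (sum over the 2x2x2 children), used on the decoder path.
upsample2 <- function(x) {
  d <- dim(x)
  i <- rep(seq_len(d[1]), each = 2)
  j <- rep(seq_len(d[2]), each = 2)
  k <- rep(seq_len(d[3]), each = 2)
  x[i, j, k, , drop = FALSE]
}

upsample2_backward <- function(dy) {
  d <- dim(dy)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0, d[3] %% 2 == 0)
  half <- c(d[1] / 2, d[2] / 2, d[3] / 2, d[4])
  dx <- array(0, half)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    dx <- dx + dy[seq(1 + a, d[1], by = 2), seq(1 + b, d[2], by = 2),
                  seq(1 + cc, d[3], by = 2), , drop = FALSE]
  }
  dx
}

# ---- batch normalization ---------------------------------------------------
# Channel-wise normalization over all voxels of the input block.  Running
# moments (momentum 0.1) are used at inference time.

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       run_mean = rep(0, channels), run_var = rep(1, channels))
}

bn_forward <- function(x, gamma, beta, state, training, eps = 1e-5,
                       momentum = 0.1) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  xm <- matrix(x, nrow = nvox, ncol = d[4])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    state$run_mean <- (1 - momentum) * state$run_mean + momentum * mu
    state$run_var <- (1 - momentum) * state$run_var + momentum * v
  } else {
    mu <- state$run_mean
    v <- state$run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, dim = d),
       state = state)
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$dim
  nvox <- prod(d[1:3])
  dym <- matrix(dy, nrow = nvox, ncol = d[4])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  # standard batch-norm gradient with batch statistics
  t1 <- sweep(dym, 2, gamma, `*`)
  dxhat_mean <- colMeans(t1)
  dxhat_xhat_mean <- colMeans(t1 * xhat)
  dx <- sweep(t1, 2, dxhat_mean) - sweep(xhat, 2, dxhat_xhat_mean, `*`)
  dx <- sweep(dx, 2, cache$inv_sd, `*`)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- optimizers ------------------------------------------------------------
# Both operate on flat named lists of numeric arrays.

optimizer_init <- function(kind, params) {
  zeros <- lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  switch(kind,
    adam = list(kind = "adam", m = zeros, v = zeros, t = 0),
    rmsprop = list(kind = "rmsprop", v = zeros),
    stop("unknown optimizer: ", kind))
}

optimizer_step <- function(opt, params, grads, lr,
                           beta1 = 0.9, beta2 = 0.999, rho = 0.9, eps = 1e-8) {
  if (opt$kind == "adam") {
    opt$t <- opt$t + 1
    for (nm in names(params)) {
      g <- grads[[nm]]
      opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
      opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
      mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
      vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  } else {
    for (nm in names(params)) {
      g <- grads[[nm]]
      opt$v[[nm]] <- rho * opt$v[[nm]] + (1 - rho) * g^2
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(opt$v[[nm]]) + eps)
    }
  }
  list(opt = opt, params = params)
}

# accumulate gradient lists (same names/shapes)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

grads_scale <- function(a, s) lapply(a, function(g) g * s)
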