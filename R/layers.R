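# Building blocks of the 3D networks: strided convolution, strided transposed
# convolution (both via im2col/col2im), batch normalization, activations,
# dropout and the Adam optimizer. Forward functions return caches that the
# matching backward functions consume; gradients are verified against finite
# differences in the test suite.
#
# Tensor convention: numeric arrays with dims (x, y, z, channels).
# Convolution weights: matrix (out_channels x k^3 * in_channels), rows
# matching the im2col row layout (kx fastest, then ky, kz, channel).
# Transposed-convolution weights: matrix (in_channels x k^3 * out_channels).

conv_out_shape <- function(shape, k, stride, pad) {
  (shape + 2L * pad - k) %/% stride + 1L
}

conv3d_forward <- function(x, W, b, k = 4L, stride = 2L, pad = 1L,
                           keep_cache = FALSE) {
  x <- as_channels(x)
  d <- dim(x)
  cols <- im2col_3d(as.double(x), as.integer(d), as.integer(k),
                    as.integer(stride), as.integer(pad))
  out_sp <- conv_out_shape(d[1:3], k, stride, pad)
  y_mat <- W %*% cols + b # b recycles down columns (length = out channels)
  y <- t(y_mat)
  dim(y) <- c(out_sp, nrow(W))
  cache <- if (keep_cache) list(cols = cols, xdim = d, W = W, k = k,
                                stride = stride, pad = pad) else NULL
  list(out = y, cache = cache)
}

conv3d_backward <- function(dy, cache) {
  dsp <- dim(dy)
  P <- prod(dsp[1:3])
  dy_mat <- t(matrix(dy, nrow = P))
  dW <- dy_mat %*% t(cache$cols)
  db <- rowSums(dy_mat)
  dcols <- crossprod(cache$W, dy_mat)
  dx <- col2im_3d(dcols, as.integer(cache$xdim), as.integer(cache$k),
                  as.integer(cache$stride), as.integer(cache$pad))
  list(dx = dx, dW = dW, db = db)
}

deconv_out_shape <- function(shape, k, stride, pad) {
  stride * (shape - 1L) + k - 2L * pad
}

deconv3d_forward <- function(x, W, b, k = 4L, stride = 2L, pad = 1L,
                             keep_cache = FALSE) {
  x <- as_channels(x)
  d <- dim(x)
  c_out <- ncol(W) %/% (k^3)
  out_sp <- deconv_out_shape(d[1:3], k, stride, pad)
  x_mat <- t(matrix(x, nrow = prod(d[1:3])))    # in_channels x P
  cols <- crossprod(W, x_mat)                    # k^3*c_out x P
  y <- col2im_3d(cols, as.integer(c(out_sp, c_out)), as.integer(k),
                 as.integer(stride), as.integer(pad))
  y <- y + rep(b, each = prod(out_sp))
  cache <- if (keep_cache) list(x_mat = x_mat, xdim = d, W = W, k = k,
                                stride = stride, pad = pad) else NULL
  list(out = y, cache = cache)
}

deconv3d_backward <- function(dy, cache) {
  d <- dim(dy)
  dcols <- im2col_3d(as.double(dy), as.integer(d), as.integer(cache$k),
                     as.integer(cache$stride), as.integer(cache$pad))
  dx_mat <- cache$W %*% dcols
  dx <- t(dx_mat)
  dim(dx) <- cache$xdim
  dW <- cache$x_mat %*% t(dcols)
  db <- colSums(matrix(dy, nrow = prod(d[1:3])))
  list(dx = dx, dW = dW, db = db)
}

# Batch normalization over the spatial voxels of each channel (batch size 1).
bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       train = TRUE, momentum = 0.1, eps = 1e-5,
                       keep_cache = FALSE) {
  d <- dim(x)
  P <- prod(d[1:3])
  C <- d[4]
  M <- matrix(x, nrow = P)
  if (train) {
    mu <- colMeans(M)
    va <- colMeans(M^2) - mu^2
    va <- pmax(va, 0)
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * va
  } else {
    mu <- running_mean
    va <- running_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- (M - rep(mu, each = P)) * rep(inv_sd, each = P)
  y <- xhat * rep(gamma, each = P) + rep(beta, each = P)
  dim(y) <- d
  cache <- if (keep_cache) list(xhat = xhat, inv_sd = inv_sd, gamma = gamma,
                                P = P, C = C, d = d) else NULL
  list(out = y, cache = cache,
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(dy, cache) {
  P <- cache$P
  dyM <- matrix(dy, nrow = P)
  xhat <- cache$xhat
  dgamma <- colSums(dyM * xhat)
  dbeta <- colSums(dyM)
  dxhat <- dyM * rep(cache$gamma, each = P)
  mean_dxhat <- colMeans(dxhat)
  mean_dxhat_xhat <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(mean_dxhat, each = P) -
           xhat * rep(mean_dxhat_xhat, each = P)) *
    rep(cache$inv_sd, each = P)
  dim(dx) <- cache$d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)
relu <- function(x) pmax(x, 0)
relu_grad <- function(x) as.numeric(x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

dropout_forward <- function(x, rate) {
  # inverted dropout; draws from the current RNG stream
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
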