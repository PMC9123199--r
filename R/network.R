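#' Generator (3D U-Net) configuration
#'
#' The generator is an encoder--decoder U-Net built from strided 3D
#' convolutions: `depth` encoder levels (kernel 4, stride 2) that halve every
#' axis, mirrored by `depth` transposed-convolution decoder levels that double
#' them, with skip concatenation from encoder level i to decoder level
#' depth - i. Feature maps double per level, capped at `8 * base_filters`.
#' Dropout acts on the first `dropout_layers` decoder levels; the final
#' activation is tanh so outputs live in `[-1, 1]` like the normalized inputs.
#'
#' @param depth Number of encoder (= decoder) levels. Default 6, the
#'   full-scale setting; tests and examples use 3--4 on small grids.
#' @param base_filters Feature maps in the first encoder level.
#' @param kernel,stride Convolution kernel size and stride per axis.
#' @param dropout_layers Leading decoder levels with dropout.
#' @param dropout_rate Dropout probability (pix2pix default 0.5).
#' @param init_std Standard deviation of the Gaussian weight initializer.
#' @return A `gan_generator_config` list.
#' @export
generator_config <- function(depth = 6L, base_filters = 64L, kernel = 4L,
                             stride = 2L, dropout_layers = 3L,
                             dropout_rate = 0.5, init_std = 0.02) {
  stopifnot(depth >= 1, base_filters >= 1, kernel >= 1, stride >= 1,
            dropout_layers >= 0, dropout_layers <= depth,
            dropout_rate >= 0, dropout_rate < 1, init_std > 0)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pad = 1L, dropout_layers = as.integer(dropout_layers),
                 dropout_rate = dropout_rate, init_std = init_std),
            class = "gan_generator_config")
}

#' Discriminator (3D PatchGAN) configuration
#'
#' The discriminator takes the conditioning volume and a candidate volume,
#' concatenated channel-wise at the input, pushes them through `n_levels`
#' stride-2 convolutions and a final stride-1 convolution to a single-channel
#' patch of independent real/fake probabilities (sigmoid), one per receptive
#' field. With the default 4 levels a padded 64x64x64 input yields the
#' 4x4x4 patch; a 64x64x16 input yields 4x4x1.
#'
#' @inheritParams generator_config
#' @param n_levels Number of stride-2 convolution levels.
#' @return A `gan_discriminator_config` list.
#' @export
discriminator_config <- function(n_levels = 4L, base_filters = 64L,
                                 kernel = 4L, stride = 2L, init_std = 0.02) {
  stopifnot(n_levels >= 1, base_filters >= 1, kernel >= 1, stride >= 1,
            init_std > 0)
  structure(list(n_levels = as.integer(n_levels),
                 base_filters = as.integer(base_filters),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pad = 1L, init_std = init_std),
            class = "gan_discriminator_config")
}

level_filters <- function(base, i) as.integer(base * min(2^(i - 1), 8))

init_conv_w <- function(c_out, c_in, k, sdv) {
  matrix(rnorm(c_out * k^3 * c_in, sd = sdv), nrow = c_out)
}
init_deconv_w <- function(c_in, c_out, k, sdv) {
  matrix(rnorm(c_in * k^3 * c_out, sd = sdv), nrow = c_in)
}

#' Build the 3D U-Net generator
#'
#' Weights are drawn from the current RNG stream (`N(0, init_std)`); seed the
#' stream for reproducible initialization. The network is fully convolutional
#' and accepts any input whose axes are divisible by `2^depth`.
#'
#' @param cfg A [generator_config()].
#' @param input_shape Integer vector of 3 voxel counts; every axis must be
#'   divisible by `2^depth`.
#' @return A `gan_generator` object (configuration, parameters, batch-norm
#'   buffers).
#' @export
build_generator <- function(cfg, input_shape) {
  stopifnot(inherits(cfg, "gan_generator_config"), length(input_shape) == 3L)
  check_divisible(input_shape, cfg$depth)
  depth <- cfg$depth
  f <- vapply(seq_len(depth), function(i) level_filters(cfg$base_filters, i),
              integer(1))
  params <- list()
  buffers <- list()
  enc_bn <- logical(depth)
  c_prev <- 1L
  for (i in seq_len(depth)) {
    nm <- paste0("enc", i)
    params[[paste0(nm, ".W")]] <- init_conv_w(f[i], c_prev, cfg$kernel,
                                              cfg$init_std)
    params[[paste0(nm, ".b")]] <- numeric(f[i])
    enc_bn[i] <- i > 1 && i < depth
    if (enc_bn[i]) {
      params[[paste0(nm, ".gamma")]] <- rnorm(f[i], 1, cfg$init_std)
      params[[paste0(nm, ".beta")]] <- numeric(f[i])
      buffers[[paste0(nm, ".rm")]] <- numeric(f[i])
      buffers[[paste0(nm, ".rv")]] <- rep(1, f[i])
    }
    c_prev <- f[i]
  }
  dec_bn <- logical(depth)
  dec_drop <- logical(depth)
  dec_out <- integer(depth)
  for (j in seq_len(depth)) {
    nm <- paste0("dec", j)
    c_in <- if (j == 1) f[depth] else 2L * f[depth - j + 2L - 1L]
    c_out <- if (j < depth) f[depth - j] else 1L
    dec_out[j] <- c_out
    params[[paste0(nm, ".W")]] <- init_deconv_w(c_in, c_out, cfg$kernel,
                                                cfg$init_std)
    params[[paste0(nm, ".b")]] <- numeric(c_out)
    dec_bn[j] <- j < depth
    dec_drop[j] <- j <= cfg$dropout_layers && j < depth
    if (dec_bn[j]) {
      params[[paste0(nm, ".gamma")]] <- rnorm(c_out, 1, cfg$init_std)
      params[[paste0(nm, ".beta")]] <- numeric(c_out)
      buffers[[paste0(nm, ".rm")]] <- numeric(c_out)
      buffers[[paste0(nm, ".rv")]] <- rep(1, c_out)
    }
  }
  structure(list(cfg = cfg, input_shape = as.integer(input_shape),
                 filters = f, enc_bn = enc_bn, dec_bn = dec_bn,
                 dec_drop = dec_drop, dec_out_channels = dec_out,
                 params = params, buffers = buffers),
            class = "gan_generator")
}

check_divisible <- function(shape, depth) {
  fac <- 2^depth
  bad <- which(shape %% fac != 0)
  if (length(bad) > 0) {
    stop(sprintf("axis %d of input shape (%s) is not divisible by 2^%d = %d",
                 bad[1], paste(shape, collapse = "x"), depth, fac))
  }
  invisible(TRUE)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
}

slice_channels <- function(x, idx) {
  d <- dim(x)
  y <- x[, , , idx, drop = FALSE]
  dim(y) <- c(d[1:3], length(idx))
  y
}

#' Run the generator forward
#'
#' @param net A `gan_generator`.
#' @param x Input volume in `[-1, 1]`, axes divisible by `2^depth`.
#' @param train Logical; `TRUE` enables dropout (drawn from the current RNG
#'   stream) and batch-statistics normalization, `FALSE` uses accumulated
#'   running statistics and no dropout.
#' @param keep_cache Keep intermediate tensors for backpropagation.
#' @return List with `out` (same shape as `x`), `cache`, and updated `buffers`.
#' @export
forward_generator <- function(net, x, train = FALSE, keep_cache = FALSE) {
  cfg <- net$cfg
  x <- as_channels(x)
  check_divisible(dim(x)[1:3], cfg$depth)
  depth <- cfg$depth
  p <- net$params
  bufs <- net$buffers
  e <- vector("list", depth)
  enc_cache <- vector("list", depth)
  h <- x
  for (i in seq_len(depth)) {
    nm <- paste0("enc", i)
    a <- if (i == 1) h else lrelu(e[[i - 1]])
    cv <- conv3d_forward(a, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]],
                         cfg$kernel, cfg$stride, cfg$pad,
                         keep_cache = keep_cache)
    t <- cv$out
    bnc <- NULL
    if (net$enc_bn[i]) {
      bn <- bn_forward(t, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                       bufs[[paste0(nm, ".rm")]], bufs[[paste0(nm, ".rv")]],
                       train = train, keep_cache = keep_cache)
      t <- bn$out
      bufs[[paste0(nm, ".rm")]] <- bn$running_mean
      bufs[[paste0(nm, ".rv")]] <- bn$running_var
      bnc <- bn$cache
    }
    e[[i]] <- t
    enc_cache[[i]] <- list(conv = cv$cache, bn = bnc)
  }
  dec_cache <- vector("list", depth)
  d_cur <- e[[depth]]
  y <- NULL
  for (j in seq_len(depth)) {
    nm <- paste0("dec", j)
    u_in <- d_cur
    a <- relu(u_in)
    dc <- deconv3d_forward(a, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]],
                           cfg$kernel, cfg$stride, cfg$pad,
                           keep_cache = keep_cache)
    t <- dc$out
    bnc <- NULL
    mask <- NULL
    if (net$dec_bn[j]) {
      bn <- bn_forward(t, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                       bufs[[paste0(nm, ".rm")]], bufs[[paste0(nm, ".rv")]],
                       train = train, keep_cache = keep_cache)
      t <- bn$out
      bufs[[paste0(nm, ".rm")]] <- bn$running_mean
      bufs[[paste0(nm, ".rv")]] <- bn$running_var
      bnc <- bn$cache
    }
    if (net$dec_drop[j] && train) {
      dp <- dropout_forward(t, cfg$dropout_rate)
      t <- dp$out
      mask <- dp$mask
    }
    dec_cache[[j]] <- list(u_in = if (keep_cache) u_in else NULL,
                           conv = dc$cache, bn = bnc, mask = mask,
                           t_channels = dim(t)[4])
    if (j < depth) {
      d_cur <- concat_channels(t, e[[depth - j]])
    } else {
      y <- tanh(t)
    }
  }
  cache <- if (keep_cache) list(e = e, enc = enc_cache, dec = dec_cache,
                                y = y, x = x) else NULL
  list(out = y, cache = cache, buffers = bufs)
}

backward_generator <- function(net, cache, dy) {
  cfg <- net$cfg
  depth <- cfg$depth
  grads <- list()
  g_e <- vector("list", depth)
  add_to <- function(cur, inc) if (is.null(cur)) inc else cur + inc
  carry <- NULL
  for (j in rev(seq_len(depth))) {
    nm <- paste0("dec", j)
    dcj <- cache$dec[[j]]
    if (j == depth) {
      dt <- dy * (1 - cache$y^2)
    } else {
      tch <- dcj$t_channels
      total_ch <- dim(carry)[4]
      dt <- slice_channels(carry, seq_len(tch))
      dskip <- slice_channels(carry, (tch + 1L):total_ch)
      g_e[[depth - j]] <- add_to(g_e[[depth - j]], dskip)
    }
    if (!is.null(dcj$mask)) dt <- dt * dcj$mask
    if (net$dec_bn[j]) {
      bb <- bn_backward(dt, dcj$bn)
      grads[[paste0(nm, ".gamma")]] <- bb$dgamma
      grads[[paste0(nm, ".beta")]] <- bb$dbeta
      dt <- bb$dx
    }
    db <- deconv3d_backward(dt, dcj$conv)
    grads[[paste0(nm, ".W")]] <- db$dW
    grads[[paste0(nm, ".b")]] <- db$db
    gin <- db$dx * relu_grad(dcj$u_in)
    if (j == 1) g_e[[depth]] <- add_to(g_e[[depth]], gin) else carry <- gin
  }
  dx <- NULL
  for (i in rev(seq_len(depth))) {
    nm <- paste0("enc", i)
    gi <- g_e[[i]]
    ecj <- cache$enc[[i]]
    if (net$enc_bn[i]) {
      bb <- bn_backward(gi, ecj$bn)
      grads[[paste0(nm, ".gamma")]] <- bb$dgamma
      grads[[paste0(nm, ".beta")]] <- bb$dbeta
      gi <- bb$dx
    }
    cb <- conv3d_backward(gi, ecj$conv)
    grads[[paste0(nm, ".W")]] <- cb$dW
    grads[[paste0(nm, ".b")]] <- cb$db
    if (i > 1) {
      g_e[[i - 1]] <- add_to(g_e[[i - 1]],
                             cb$dx * lrelu_grad(cache$e[[i - 1]]))
    } else {
      dx <- cb$dx
    }
  }
  list(grads = grads, dx = dx)
}

#' Expected PatchGAN output shape for an input shape
#'
#' Traces the stride plan of the discriminator over `input_shape`. Errors if
#' any level would reduce an axis to a non-positive size.
#'
#' @param cfg A [discriminator_config()].
#' @param input_shape Integer vector of 3 voxel counts.
#' @return Integer vector of 3: the patch dimensions.
#' @export
discriminator_patch_shape <- function(cfg, input_shape) {
  shp <- as.integer(input_shape)
  for (i in seq_len(cfg$n_levels)) {
    shp <- conv_out_shape(shp, cfg$kernel, cfg$stride, cfg$pad)
    if (any(shp < 1)) {
      stop(sprintf("input shape too small for %d stride-%d levels (axis %d)",
                   cfg$n_levels, cfg$stride, which(shp < 1)[1]))
    }
  }
  shp # final stride-1 convolution preserves the shape
}

#' Build the 3D PatchGAN discriminator
#'
#' @param cfg A [discriminator_config()].
#' @param input_shape Integer vector of 3 voxel counts (per input volume; the
#'   two inputs are concatenated channel-wise).
#' @return A `gan_discriminator` object.
#' @export
build_discriminator <- function(cfg, input_shape) {
  stopifnot(inherits(cfg, "gan_discriminator_config"),
            length(input_shape) == 3L)
  patch <- discriminator_patch_shape(cfg, input_shape)
  L <- cfg$n_levels
  f <- vapply(seq_len(L), function(i) level_filters(cfg$base_filters, i),
              integer(1))
  params <- list()
  buffers <- list()
  lay_bn <- logical(L)
  c_prev <- 2L # condition + candidate
  for (i in seq_len(L)) {
    nm <- paste0("lay", i)
    params[[paste0(nm, ".W")]] <- init_conv_w(f[i], c_prev, cfg$kernel,
                                              cfg$init_std)
    params[[paste0(nm, ".b")]] <- numeric(f[i])
    lay_bn[i] <- i > 1
    if (lay_bn[i]) {
      params[[paste0(nm, ".gamma")]] <- rnorm(f[i], 1, cfg$init_std)
      params[[paste0(nm, ".beta")]] <- numeric(f[i])
      buffers[[paste0(nm, ".rm")]] <- numeric(f[i])
      buffers[[paste0(nm, ".rv")]] <- rep(1, f[i])
    }
    c_prev <- f[i]
  }
  params[["out.W"]] <- init_conv_w(1L, c_prev, 3L, cfg$init_std)
  params[["out.b"]] <- numeric(1L)
  structure(list(cfg = cfg, input_shape = as.integer(input_shape),
                 patch_shape = patch, filters = f, lay_bn = lay_bn,
                 params = params, buffers = buffers),
            class = "gan_discriminator")
}

#' Run the discriminator forward
#'
#' @param net A `gan_discriminator`.
#' @param cond Conditioning volume (the biased source), `[-1, 1]`.
#' @param cand Candidate volume (real target or generator output).
#' @param train Logical; batch-statistics vs running-statistics normalization.
#' @param keep_cache Keep tensors for backpropagation.
#' @return List with `probs` (patch of probabilities in (0, 1)), `logits`,
#'   `cache` and updated `buffers`.
#' @export
forward_discriminator <- function(net, cond, cand, train = FALSE,
                                  keep_cache = FALSE) {
  cfg <- net$cfg
  cond <- as_channels(cond)
  cand <- as_channels(cand)
  if (!identical(dim(cond), dim(cand))) {
    stop("condition and candidate volumes must share the same shape")
  }
  x <- concat_channels(cond, cand)
  p <- net$params
  bufs <- net$buffers
  L <- cfg$n_levels
  lay_cache <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    nm <- paste0("lay", i)
    cv <- conv3d_forward(h, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]],
                         cfg$kernel, cfg$stride, cfg$pad,
                         keep_cache = keep_cache)
    t <- cv$out
    bnc <- NULL
    if (net$lay_bn[i]) {
      bn <- bn_forward(t, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                       bufs[[paste0(nm, ".rm")]], bufs[[paste0(nm, ".rv")]],
                       train = train, keep_cache = keep_cache)
      t <- bn$out
      bufs[[paste0(nm, ".rm")]] <- bn$running_mean
      bufs[[paste0(nm, ".rv")]] <- bn$running_var
      bnc <- bn$cache
    }
    lay_cache[[i]] <- list(conv = cv$cache, bn = bnc,
                           pre_act = if (keep_cache) t else NULL)
    h <- lrelu(t)
  }
  ov <- conv3d_forward(h, p[["out.W"]], p[["out.b"]], 3L, 1L, 1L,
                       keep_cache = keep_cache)
  logits <- drop_channel(ov$out)
  probs <- sigmoid(logits)
  cache <- if (keep_cache) list(lay = lay_cache, out_conv = ov$cache,
                                n_cond = dim(cond)[4]) else NULL
  list(probs = probs, logits = logits, cache = cache, buffers = bufs)
}

backward_discriminator <- function(net, cache, dlogits) {
  cfg <- net$cfg
  grads <- list()
  dlog <- as_channels(dlogits)
  cb <- conv3d_backward(dlog, cache$out_conv)
  grads[["out.W"]] <- cb$dW
  grads[["out.b"]] <- cb$db
  g <- cb$dx
  for (i in rev(seq_len(cfg$n_levels))) {
    nm <- paste0("lay", i)
    lc <- cache$lay[[i]]
    g <- g * lrelu_grad(lc$pre_act)
    if (net$lay_bn[i]) {
      bb <- bn_backward(g, lc$bn)
      grads[[paste0(nm, ".gamma")]] <- bb$dgamma
      grads[[paste0(nm, ".beta")]] <- bb$dbeta
      g <- bb$dx
    }
    cc <- conv3d_backward(g, lc$conv)
    grads[[paste0(nm, ".W")]] <- cc$dW
    grads[[paste0(nm, ".b")]] <- cc$db
    g <- cc$dx
  }
  nc <- cache$n_cond
  total <- dim(g)[4]
  list(grads = grads,
       d_cond = slice_channels(g, seq_len(nc)),
       d_cand = slice_channels(g, (nc + 1L):total))
}

#' Count trainable parameters of a network
#'
#' @param net A `gan_generator` or `gan_discriminator`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

#' Save / load network weights
#'
#' Checkpoints bundle generator and discriminator parameters, batch-norm
#' buffers, configurations and the epoch/iteration stamp into one file.
#'
#' @param path File path.
#' @param netG,netD Generator and discriminator objects.
#' @param epoch,iteration Training progress stamps.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `netG`, `netD`, `epoch`, `iteration`.
#' @export
save_checkpoint <- function(path, netG, netD = NULL, epoch = NA_integer_,
                            iteration = NA_integer_) {
  saveRDS(list(netG = netG, netD = netD, epoch = epoch,
               iteration = iteration), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  readRDS(path)
}
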