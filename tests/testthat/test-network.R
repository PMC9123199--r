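ep <- asNamespace("epigan")

test_that("generator preserves the input shape and the [-1, 1] range", {
  set.seed(20)
  cfg <- generator_config(depth = 3, base_filters = 4, dropout_layers = 1)
  net <- build_generator(cfg, c(16, 16, 16))
  for (shp in list(c(16, 16, 16), c(24, 16, 8), c(8, 8, 16))) {
    x <- array(rnorm(prod(shp)), shp)
    out <- forward_generator(net, x)$out
    expect_identical(dim(out), c(as.integer(shp), 1L))
    expect_true(all(out >= -1 & out <= 1))
  }
})

test_that("non-divisible input shapes are rejected naming the axis", {
  cfg <- generator_config(depth = 4, base_filters = 4)
  expect_error(build_generator(cfg, c(60, 64, 16)), "axis 1")
  net <- build_generator(cfg, c(64, 64, 16))
  expect_error(forward_generator(net, array(0, c(64, 64, 15))), "axis 3")
})

test_that("a depth-4 generator reduces a 16-cube to a unit bottleneck", {
  set.seed(21)
  cfg <- generator_config(depth = 4, base_filters = 4)
  net <- build_generator(cfg, c(16, 16, 16))
  x <- array(rnorm(16^3), c(16, 16, 16))
  fw <- forward_generator(net, x, keep_cache = TRUE)
  expect_identical(dim(fw$cache$e[[4]])[1:3], c(1L, 1L, 1L))
  expect_identical(dim(fw$out), c(16L, 16L, 16L, 1L))
})

test_that("full generator backpropagation matches finite differences", {
  set.seed(22)
  cfg <- generator_config(depth = 3, base_filters = 2, dropout_layers = 0)
  net <- build_generator(cfg, c(8, 8, 8))
  x <- array(rnorm(8^3), c(8, 8, 8))
  fw <- forward_generator(net, x, train = TRUE, keep_cache = TRUE)
  dy <- array(rnorm(length(fw$out)), dim(fw$out))
  bk <- ep$backward_generator(net, fw$cache, dy)
  for (nm in c("enc1.W", "enc2.gamma", "dec1.W", "dec3.b")) {
    p <- net$params[[nm]]
    idx <- sample(length(p), min(3, length(p)))
    f <- function(v) {
      n2 <- net
      n2$params[[nm]] <- if (is.matrix(p)) matrix(v, nrow(p)) else v
      sum(forward_generator(n2, x, train = TRUE)$out * dy)
    }
    expect_equal(fd_grad(f, as.vector(p), idx), as.vector(bk$grads[[nm]])[idx],
                 tolerance = 1e-4)
  }
})

test_that("discriminator patch shape follows the stride plan", {
  cfg <- discriminator_config(n_levels = 4, base_filters = 4)
  expect_identical(discriminator_patch_shape(cfg, c(64, 64, 16)),
                   c(4L, 4L, 1L))
  expect_identical(discriminator_patch_shape(cfg, c(64, 64, 64)),
                   c(4L, 4L, 4L))
  expect_error(discriminator_patch_shape(cfg, c(8, 8, 8)), "too small")
})

test_that("discriminator outputs per-patch probabilities responsive to the candidate", {
  set.seed(23)
  cfg <- discriminator_config(n_levels = 2, base_filters = 4)
  net <- build_discriminator(cfg, c(16, 16, 16))
  cond <- array(rnorm(16^3), c(16, 16, 16))
  x1 <- array(rnorm(16^3), c(16, 16, 16))
  x2 <- array(rnorm(16^3), c(16, 16, 16))
  o1 <- forward_discriminator(net, cond, x1)$probs
  o2 <- forward_discriminator(net, cond, x2)$probs
  expect_identical(dim(o1), c(4L, 4L, 4L))
  expect_true(all(o1 > 0 & o1 < 1))
  expect_gt(max(abs(o1 - o2)), 0) # conditioning on the candidate is not degenerate
  expect_error(forward_discriminator(net, cond, array(0, c(8, 8, 8))),
               "same shape")
})

test_that("discriminator backpropagation matches finite differences", {
  set.seed(24)
  cfg <- discriminator_config(n_levels = 2, base_filters = 2)
  net <- build_discriminator(cfg, c(8, 8, 8))
  cond <- array(rnorm(8^3), c(8, 8, 8))
  cand <- array(rnorm(8^3), c(8, 8, 8))
  fw <- forward_discriminator(net, cond, cand, train = TRUE, keep_cache = TRUE)
  dl <- array(rnorm(length(fw$logits)), dim(fw$logits))
  bk <- ep$backward_discriminator(net, fw$cache, dl)
  f_c <- function(v) sum(forward_discriminator(net, cond, array(v, dim(cand)),
                                               train = TRUE)$logits * dl)
  idx <- sample(length(cand), 10)
  expect_equal(fd_grad(f_c, as.vector(cand), idx), as.vector(bk$d_cand)[idx],
               tolerance = 1e-5)
  p <- net$params[["lay2.W"]]
  f_w <- function(v) {
    n2 <- net
    n2$params[["lay2.W"]] <- matrix(v, nrow(p))
    sum(forward_discriminator(n2, cond, cand, train = TRUE)$logits * dl)
  }
  idx <- sample(length(p), 10)
  expect_equal(fd_grad(f_w, as.vector(p), idx), as.vector(bk$grads[["lay2.W"]])[idx],
               tolerance = 1e-5)
})

test_that("parameter count grows strictly with the filter budget", {
  set.seed(25)
  n4 <- build_generator(generator_config(depth = 3, base_filters = 4), c(8, 8, 8))
  n8 <- build_generator(generator_config(depth = 3, base_filters = 8), c(8, 8, 8))
  expect_gt(n_parameters(n8), n_parameters(n4))
})

test_that("checkpoint serialization reproduces forward outputs exactly", {
  set.seed(26)
  gcfg <- generator_config(depth = 2, base_filters = 4, dropout_layers = 0)
  dcfg <- discriminator_config(n_levels = 1, base_filters = 4)
  netG <- build_generator(gcfg, c(8, 8, 8))
  netD <- build_discriminator(dcfg, c(8, 8, 8))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(path, netG, netD, epoch = 7, iteration = 123)
  ck <- load_checkpoint(path)
  expect_identical(ck$epoch, 7)
  x <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(forward_generator(ck$netG, x)$out,
                   forward_generator(netG, x)$out)
  expect_identical(forward_discriminator(ck$netD, x, x)$probs,
                   forward_discriminator(netD, x, x)$probs)
  expect_error(load_checkpoint(tempfile()), "not found")
  unlink(path)
})
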