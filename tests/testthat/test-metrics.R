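test_that("cosine angle distance matches hand evaluations and invariances", {
  expect_equal(cad(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cad(c(1, 0), c(0, 1)), 0)
  expect_equal(cad(c(1, 2, 3), c(4, 5, 6)), 32 / (sqrt(14) * sqrt(77)),
               tolerance = 1e-12)
  expect_error(cad(c(0, 0), c(1, 1)), "zero")
  set.seed(40)
  for (i in 1:10) {
    a <- rnorm(50); b <- rnorm(50); k <- runif(1, 0.1, 10)
    expect_equal(cad(a, b), cad(b, a), tolerance = 1e-12)
    expect_equal(cad(k * a, b), cad(a, b), tolerance = 1e-12)
    expect_true(cad(a, b) >= -1 && cad(a, b) <= 1)
  }
})

test_that("L2, MSE and PSNR are interconvertible as documented", {
  expect_equal(l2_norm(c(1, 1), c(1, 1)), 0)
  expect_equal(l2_norm(rep(0, 4), rep(1, 4)), 2)
  expect_equal(psnr(c(0.5, 0.5), c(0.5, 0.5)), Inf)
  set.seed(41)
  for (i in 1:10) {
    n <- sample(10:100, 1)
    a <- runif(n); b <- runif(n)
    expect_equal(l2_norm(a, b)^2, n * mse(a, b), tolerance = 1e-10)
    expect_equal(psnr(a, b), 10 * log10(1 / mse(a, b)), tolerance = 1e-10)
    expect_equal(l2_norm(a, b), sqrt(sum((a - b)^2)), tolerance = 1e-12)
  }
})

test_that("Gaussian window weights are circular-symmetric and unit sum", {
  for (ws in list(c(7L, 7L, 7L), c(5L, 3L, 7L), c(9L, 9L, 9L))) {
    w <- gaussian_window(ws, 1.5)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_identical(dim(w), ws)
    # symmetric under reflection along each axis
    expect_equal(w, w[rev(seq_len(ws[1])), , ], tolerance = 1e-12)
  }
})

test_that("MSSIM equals 1 for identical volumes and is symmetric", {
  set.seed(42)
  A <- array(runif(14^3), c(14, 14, 14))
  B <- array(runif(14^3), c(14, 14, 14))
  expect_equal(mssim(A, A)$mssim, 1, tolerance = 1e-9)
  expect_equal(mssim(A, B)$mssim, mssim(B, A)$mssim, tolerance = 1e-9)
  expect_error(mssim(A, array(0, c(6, 6, 6))), "shapes")
  expect_error(mssim(array(0, c(5, 5, 5)), array(0, c(5, 5, 5))),
               "window")
})

test_that("MSSIM window count reproduces the 58 x 10 x 58 accounting", {
  A <- array(runif(64 * 16 * 64), c(64, 16, 64))
  res <- mssim(A, A)
  expect_identical(res$n_windows, 58L * 10L * 58L)
})

test_that("constant-plateau volumes give the closed-form luminance value", {
  A <- array(0.2, c(8, 8, 8))
  B <- array(0.4, c(8, 8, 8))
  expected <- (2 * 0.2 * 0.4 + 1e-4) / (0.2^2 + 0.4^2 + 1e-4)
  expect_equal(mssim(A, B)$mssim, expected, tolerance = 1e-9)
})

test_that("separable MSSIM matches the brute-force window oracle", {
  set.seed(43)
  for (i in 1:3) {
    A <- array(runif(12^3), c(12, 12, 12))
    B <- pmin(pmax(A + rnorm(12^3, sd = 0.1), 0), 1)
    expect_equal(mssim(A, B)$mssim, naive_mssim(A, B), tolerance = 1e-6)
  }
})

test_that("Dice follows the overlap arithmetic with a strict threshold", {
  m <- array(0, c(4, 4, 1))
  m[1:2, 1:2, 1] <- 1
  expect_equal(dice(m, m), 1)
  n <- array(0, c(4, 4, 1))
  n[3:4, 3:4, 1] <- 1
  expect_equal(dice(m, n), 0)
  # |p| = 4, |p_hat| = 6, overlap 3 -> 2*3/10
  p <- array(0, c(10, 1, 1)); p[1:4, 1, 1] <- 1
  ph <- array(0, c(10, 1, 1)); ph[2:7, 1, 1] <- 1
  expect_equal(dice(p, ph), 0.6)
  # strictly-greater binarization: values at the threshold count as background
  q <- array(0.05, c(2, 2, 2)); q[1] <- 0.06
  expect_equal(dice(q, q), 1) # single voxel above threshold in both
  expect_error(dice(array(0, c(2, 2, 2)), array(0.04, c(2, 2, 2))), "empty")
})

test_that("Dice decreases monotonically as overlap is removed", {
  set.seed(44)
  p <- array(as.numeric(runif(6^3) < 0.4), c(6, 6, 6))
  ph <- p
  on <- which(ph > 0)
  prev <- dice(p, ph)
  for (i in sample(on, 10)) {
    ph[i] <- 0
    cur <- dice(p, ph)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("metric report aggregates match an independent two-pass summary", {
  set.seed(45)
  pairs <- lapply(1:4, function(i) {
    t <- array(runif(10^3), c(10, 10, 10))
    list(target = t, prediction = pmin(pmax(t + rnorm(10^3, sd = 0.05), 0), 1),
         id = paste0("v", i))
  })
  rep <- metric_report(pairs)
  expect_identical(nrow(rep$per_pair), 4L)
  expect_true(all(is.na(rep$per_pair$error)))
  for (m in c("cad", "l2", "mssim", "dice")) {
    vals <- rep$per_pair[[m]]
    srow <- rep$summary[rep$summary$metric == m, ]
    expect_equal(srow$mean, sum(vals) / length(vals), tolerance = 1e-12)
    expect_equal(srow$sd,
                 sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1)),
                 tolerance = 1e-12)
    expect_equal(srow$max, max(vals))
    expect_equal(srow$min, min(vals))
  }
})

test_that("a perfect prediction scores 1/1/1 with zero distance", {
  t <- array(runif(8^3), c(8, 8, 8))
  rep <- metric_report(list(list(target = t, prediction = t)))
  row <- rep$per_pair
  expect_equal(row$cad, 1)
  expect_equal(row$l2, 0)
  expect_equal(row$mssim, 1, tolerance = 1e-9)
  expect_equal(row$dice, 1)
})

test_that("per-pair failures are recorded rather than dropped", {
  t <- array(runif(8^3), c(8, 8, 8))
  bad <- list(target = array(0, c(8, 8, 8)), prediction = array(0, c(8, 8, 8)))
  rep <- metric_report(list(list(target = t, prediction = t), bad))
  expect_true(is.na(rep$per_pair$error[1]))
  expect_false(is.na(rep$per_pair$error[2]))
  expect_equal(rep$per_pair$cad[1], 1)
})
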