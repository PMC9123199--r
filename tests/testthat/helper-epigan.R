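# Shared fixtures: a miniature phantom world, tiny network configurations,
# and brute-force metric oracles kept deliberately independent of the package
# implementations they check.

# 16^3 miniature head used by the training smoke tests.
toy_base_spec <- function(noise_sigma = 0.03) {
  phantom_spec(grid_shape = c(16L, 16L, 16L), brain_axes = c(4.5, 5, 3),
               shell_thickness = 1, noise_sigma = noise_sigma)
}

# 8^3 micro head for fast accounting/determinism tests.
micro_spec <- function(seed = 1L, modality = "GE") {
  phantom_spec(grid_shape = c(8L, 8L, 8L), brain_axes = c(2.2, 2.4, 1.6),
               shell_thickness = 0.6, modality = modality,
               external_phantom = FALSE, phantom_radius = c(1.5, 1.5, 0.5),
               noise_sigma = 0.02, seed = seed)
}

micro_pairs <- function(n, seed0 = 100L) {
  lapply(seq_len(n), function(i) make_pair(micro_spec(seed = seed0 + i)))
}

micro_gcfg <- function(dropout_layers = 1L, ...) {
  generator_config(depth = 2L, base_filters = 4L,
                   dropout_layers = dropout_layers, ...)
}

micro_dcfg <- function(...) {
  discriminator_config(n_levels = 1L, base_filters = 4L, ...)
}

# Brute-force windowed MSSIM: explicit loop over window origins, direct
# weighted moments. Slow but written independently of the separable-filter
# implementation.
naive_mssim <- function(A, B, window = c(7L, 7L, 7L), sd = 1.5,
                        C1 = 1e-4, C2 = 9e-4, C3 = 4.5e-4) {
  ks <- lapply(window, function(n) dnorm(seq_len(n) - (n + 1) / 2, sd = sd))
  w <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
  w <- as.vector(w / sum(w))
  d <- dim(A)
  vals <- c()
  for (iz in seq_len(d[3] - window[3] + 1)) {
    for (iy in seq_len(d[2] - window[2] + 1)) {
      for (ix in seq_len(d[1] - window[1] + 1)) {
        a <- as.vector(A[ix:(ix + window[1] - 1), iy:(iy + window[2] - 1),
                         iz:(iz + window[3] - 1)])
        b <- as.vector(B[ix:(ix + window[1] - 1), iy:(iy + window[2] - 1),
                         iz:(iz + window[3] - 1)])
        muA <- sum(w * a); muB <- sum(w * b)
        sA2 <- sum(w * (a - muA)^2); sB2 <- sum(w * (b - muB)^2)
        sAB <- sum(w * (a - muA) * (b - muB))
        l <- (2 * muA * muB + C1) / (muA^2 + muB^2 + C1)
        cc <- (2 * sqrt(sA2) * sqrt(sB2) + C2) / (sA2 + sB2 + C2)
        ss <- (sAB + C3) / (sqrt(sA2) * sqrt(sB2) + C3)
        vals <- c(vals, l * cc * ss)
      }
    }
  }
  mean(vals)
}

# Central finite-difference gradient of f at x, over the given flat indices.
fd_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, numeric(1))
}
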