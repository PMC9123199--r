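# Volumetric similarity suite: cosine angle distance, L2 norm (with MSE and
# PSNR, which are interconvertible with it: L2^2 = N * MSE and
# PSNR = 10 log10(peak^2 / MSE)), Gaussian-windowed MSSIM and the Dice index.
# Metrics operate on whole volumes, background included, on the [0, 1]
# display scale.

#' Cosine angle distance between two volumes
#'
#' `CAD(A, B) = A . B / (||A|| ||B||)` over the flattened voxel arrays;
#' range `[-1, 1]`, 1 iff positively collinear. Symmetric and invariant to
#' positive rescaling of either argument.
#'
#' @param a,b Numeric arrays/vectors of equal length with nonzero norm.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' cad(c(1, 2, 3), c(4, 5, 6)) # 32 / (sqrt(14) * sqrt(77))
cad <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("cad: volumes have different sizes")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cad: undefined for an all-zero volume")
  sum(a * b) / (na * nb)
}

#' L2 norm (Euclidean distance) between two volumes
#'
#' `sqrt(sum((a_i - b_i)^2))`; 0 iff identical.
#'
#' @inheritParams cad
#' @return Non-negative scalar.
#' @export
l2_norm <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("l2_norm: volumes have different sizes")
  sqrt(sum((a - b)^2))
}

#' @rdname l2_norm
#' @export
mse <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("mse: volumes have different sizes")
  mean((a - b)^2)
}

#' @rdname l2_norm
#' @param peak Peak intensity for PSNR; 1 on display-rescaled volumes.
#' @export
psnr <- function(a, b, peak = 1) {
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' MSSIM configuration
#'
#' @param window_shape Sliding-window voxels per axis (default 7x7x7; with
#'   stride 1 and no padding this reproduces the 58x10x58 window count on a
#'   (64, 16, 64) grid).
#' @param gaussian_sd SD of the circular-symmetric Gaussian weights, samples.
#' @param C1,C2,C3 Stabilizing constants of the luminance, contrast and
#'   structure factors.
#' @param alpha,beta,gamma Exponents of the three factors.
#' @return An `mssim_config` list.
#' @export
mssim_config <- function(window_shape = c(7L, 7L, 7L), gaussian_sd = 1.5,
                         C1 = 1e-4, C2 = 9e-4, C3 = 4.5e-4,
                         alpha = 1, beta = 1, gamma = 1) {
  stopifnot(length(window_shape) == 3L, all(window_shape >= 1),
            gaussian_sd > 0, C1 > 0, C2 > 0, C3 > 0,
            alpha >= 0, beta >= 0, gamma >= 0)
  structure(list(window_shape = as.integer(window_shape),
                 gaussian_sd = gaussian_sd, C1 = C1, C2 = C2, C3 = C3,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "mssim_config")
}

#' Unit-sum Gaussian window weights
#'
#' The separable circular-symmetric Gaussian over the window grid, normalized
#' so the weights sum to 1.
#'
#' @param window_shape Integer length-3 window extents.
#' @param gaussian_sd Standard deviation in samples.
#' @return 3D array of weights summing to 1.
#' @export
gaussian_window <- function(window_shape = c(7L, 7L, 7L), gaussian_sd = 1.5) {
  ks <- lapply(window_shape, function(n) {
    off <- seq_len(n) - (n + 1) / 2
    dnorm(off, sd = gaussian_sd)
  })
  w <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
  w / sum(w)
}

# Valid- or same-mode 1D convolution along one axis of a 3D array, done as a
# banded-matrix product so the separable Gaussian moments are cheap.
conv_axis <- function(arr, kern, axis, mode = c("valid", "same")) {
  mode <- match.arg(mode)
  k <- length(kern)
  perm <- c(axis, setdiff(1:3, axis))
  a2 <- aperm(arr, perm)
  d2 <- dim(a2)
  n <- d2[1]
  if (mode == "valid") {
    if (k > n) stop("window larger than volume along axis ", axis)
    K <- matrix(0, n - k + 1, n)
    for (i in seq_len(n - k + 1)) K[i, i:(i + k - 1)] <- kern
  } else {
    h <- (k - 1) %/% 2
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - h):(i - h + k - 1)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- kern[ok]
    }
  }
  out <- K %*% matrix(a2, nrow = n)
  dim(out) <- c(nrow(K), d2[2], d2[3])
  aperm(out, order(perm))
}

sep_window_mean <- function(arr, kerns) {
  out <- arr
  for (axis in 1:3) out <- conv_axis(out, kerns[[axis]], axis, mode = "valid")
  out
}

#' Mean structural similarity (MSSIM) of two volumes
#'
#' Slides the Gaussian-weighted window over the volumes with stride 1 (no
#' padding: windows lie fully inside). Per window the luminance, contrast and
#' structure factors are computed from weighted population moments
#' (`mu`, `sigma`, `sigma_AB`); SSIM is their product under the configured
#' exponents, and MSSIM is the unweighted mean over all `M` windows.
#'
#' @param A,B Numeric 3D arrays of equal shape, at least as large as the
#'   window along every axis.
#' @param cfg An [mssim_config()].
#' @return List with `mssim` (scalar in `[-1, 1]`) and `n_windows` (`M`).
#' @export
mssim <- function(A, B, cfg = mssim_config()) {
  if (!identical(dim(A), dim(B))) stop("mssim: volumes have different shapes")
  ws <- cfg$window_shape
  if (any(dim(A) < ws)) {
    stop(sprintf("mssim: window (%s) larger than volume (%s)",
                 paste(ws, collapse = "x"), paste(dim(A), collapse = "x")))
  }
  kerns <- lapply(ws, function(n) {
    off <- seq_len(n) - (n + 1) / 2
    k <- dnorm(off, sd = cfg$gaussian_sd)
    k / sum(k)
  })
  muA <- sep_window_mean(A, kerns)
  muB <- sep_window_mean(B, kerns)
  sAA <- pmax(sep_window_mean(A * A, kerns) - muA^2, 0)
  sBB <- pmax(sep_window_mean(B * B, kerns) - muB^2, 0)
  sAB <- sep_window_mean(A * B, kerns) - muA * muB
  sigA <- sqrt(sAA)
  sigB <- sqrt(sBB)
  l <- (2 * muA * muB + cfg$C1) / (muA^2 + muB^2 + cfg$C1)
  cc <- (2 * sigA * sigB + cfg$C2) / (sAA + sBB + cfg$C2)
  ss <- (sAB + cfg$C3) / (sigA * sigB + cfg$C3)
  ssim <- l^cfg$alpha * cc^cfg$beta * ss^cfg$gamma
  list(mssim = mean(ssim), n_windows = length(ssim))
}

#' Dice overlap of two volumes after intensity thresholding
#'
#' Binarizes both inputs at `threshold` (strictly greater than) and returns
#' `2 |p & phat| / (|p| + |phat|)`. Pre-binarized masks pass through the
#' default threshold unchanged. Both masks empty is reported as an error
#' (the ratio is undefined).
#'
#' @param target,pred Numeric arrays on the `[0, 1]` display scale (or binary
#'   masks).
#' @param threshold Binarization threshold (default 0.05).
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(target, pred, threshold = 0.05) {
  if (!identical(dim(target), dim(pred))) {
    stop("dice: volumes have different shapes")
  }
  p <- target > threshold
  ph <- pred > threshold
  denom <- sum(p) + sum(ph)
  if (denom == 0) stop("dice: both masks are empty; overlap is undefined")
  2 * sum(p & ph) / denom
}

#' Per-pair similarity metrics with cohort aggregates
#'
#' Computes CAD, L2 norm, MSE, PSNR, MSSIM and Dice for each
#' (target, prediction) pair, plus the cohort mean, SD, max and min per
#' metric. Per-pair failures (e.g. degenerate inputs) are recorded in the
#' `error` column rather than dropped.
#'
#' @param pairs List of lists with elements `target` and `prediction`
#'   (volumes on the `[0, 1]` display scale), optionally `id` and `modality`.
#' @param cfg An [mssim_config()].
#' @param dice_threshold Binarization threshold for the Dice index.
#' @return A `metric_report`: list with `per_pair` and `summary` tibbles.
#' @export
metric_report <- function(pairs, cfg = mssim_config(), dice_threshold = 0.05) {
  stopifnot(length(pairs) >= 1)
  rows <- purrr::map_dfr(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    id <- if (!is.null(p$id)) p$id else sprintf("pair%03d", i)
    modality <- if (!is.null(p$modality)) p$modality else NA_character_
    res <- tryCatch({
      tibble(id = id, modality = modality,
             cad = cad(p$target, p$prediction),
             l2 = l2_norm(p$target, p$prediction),
             mse = mse(p$target, p$prediction),
             psnr = psnr(p$target, p$prediction),
             mssim = mssim(p$target, p$prediction, cfg)$mssim,
             dice = dice(p$target, p$prediction, dice_threshold),
             error = NA_character_)
    }, error = function(e) {
      tibble(id = id, modality = modality, cad = NA_real_, l2 = NA_real_,
             mse = NA_real_, psnr = NA_real_, mssim = NA_real_,
             dice = NA_real_, error = conditionMessage(e))
    })
    res
  })
  long <- tidyr::pivot_longer(
    rows[, c("id", "cad", "l2", "mse", "psnr", "mssim", "dice")],
    -"id", names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    max = max(.data$value, na.rm = TRUE),
    min = min(.data$value, na.rm = TRUE),
    .groups = "drop")
  structure(list(per_pair = rows, summary = summary),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Similarity metric report over", nrow(x$per_pair), "pairs\n")
  print(x$summary)
  invisible(x)
}
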