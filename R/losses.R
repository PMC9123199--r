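# The cGAN + L1 objective. The discriminator maximizes
#   E_{c,x}[log D(c, x)] + E_c[log(1 - D(c, G(c)))]
# (implemented as minimizing the negated patch means); the generator minimizes
# the non-saturating adversarial term -E_c[log D(c, G(c))] plus
# lambda * mean |x - G(c)|. Probabilities are clamped to [eps, 1 - eps]
# before logs so all loss values are finite.

PROB_EPS <- 1e-7

clamp_prob <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

#' Mean absolute (L1) reconstruction loss
#'
#' The expectation form of the L1 distance: the per-voxel mean of
#' `|x - x_fake|`, which keeps the weighting `lambda = 100` independent of
#' grid size.
#'
#' @param x,x_fake Equal-shaped numeric arrays.
#' @return Non-negative scalar; 0 iff the arrays are identical.
#' @export
#' @examples
#' l1_loss(array(1, c(2, 2, 2)), array(0, c(2, 2, 2))) # 1
l1_loss <- function(x, x_fake) {
  x <- as_channels(x)
  x_fake <- as_channels(x_fake)
  if (!identical(dim(x), dim(x_fake))) {
    stop("l1_loss: volumes have different shapes")
  }
  mean(abs(x - x_fake))
}

#' Discriminator loss from probability patches
#'
#' Pure form of the discriminator objective, computed from two patches of
#' probabilities (no network involved): useful both inside the training loop
#' and as an oracle surface. A patch that is 0.5 everywhere gives
#' `2 * log(2)`.
#'
#' @param p_real Patch of probabilities for the (condition, target) pair.
#' @param p_fake Patch of probabilities for the (condition, generated) pair.
#' @return List with `d_real` (`-mean log p_real`), `d_fake`
#'   (`-mean log(1 - p_fake)`) and `total`.
#' @export
d_loss_from_probs <- function(p_real, p_fake) {
  d_real <- -mean(log(clamp_prob(p_real)))
  d_fake <- -mean(log(1 - clamp_prob(p_fake)))
  list(d_real = d_real, d_fake = d_fake, total = d_real + d_fake)
}

#' Generator loss from a probability patch and a volume pair
#'
#' @param p_fake Patch of probabilities for the (condition, generated) pair.
#' @param x,x_fake Target and generated volumes.
#' @param lambda Weight of the L1 term (default 100).
#' @return List with `g_adv` (`-mean log p_fake`), `g_l1`, `lambda`, `total`.
#' @export
g_loss_from_probs <- function(p_fake, x, x_fake, lambda = 100) {
  stopifnot(lambda >= 0)
  g_adv <- -mean(log(clamp_prob(p_fake)))
  g_l1 <- l1_loss(x, x_fake)
  list(g_adv = g_adv, g_l1 = g_l1, lambda = lambda,
       total = g_adv + lambda * g_l1)
}

#' Discriminator loss for a conditioned volume triple
#'
#' Runs the discriminator on the real pair `(c, x)` and the fake pair
#' `(c, x_fake)` (inference-mode normalization; no state is mutated) and
#' returns the two negated log-mean terms the discriminator minimizes.
#'
#' @param netD A `gan_discriminator`.
#' @param cond Conditioning (source) volume.
#' @param x Real target volume.
#' @param x_fake Generated volume.
#' @return List with `d_real`, `d_fake`, `total`.
#' @export
loss_discriminator <- function(netD, cond, x, x_fake) {
  pr <- forward_discriminator(netD, cond, x, train = FALSE)$probs
  pf <- forward_discriminator(netD, cond, x_fake, train = FALSE)$probs
  d_loss_from_probs(pr, pf)
}

#' Generator loss for a conditioned volume triple
#'
#' @inheritParams loss_discriminator
#' @param lambda Weight of the L1 term.
#' @return List with `g_adv`, `g_l1`, `lambda`, `total`.
#' @export
loss_generator <- function(netD, cond, x, x_fake, lambda = 100) {
  pf <- forward_discriminator(netD, cond, x_fake, train = FALSE)$probs
  g_loss_from_probs(pf, x, x_fake, lambda)
}
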