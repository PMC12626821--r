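# Hybrid segmentation objective: L = lambda * L_CE + (1 - lambda) * L_FL,
# with L_CE the per-pixel cross-entropy of the true class and L_FL the focal
# loss alpha * (1 - p_t)^gamma * (-log p_t), both averaged over pixels.

LOSS_EPS <- 1e-7

#' Loss configuration
#'
#' @param lambda mixing weight in `[0, 1]` between cross-entropy (`lambda`)
#'   and focal loss (`1 - lambda`).
#' @param alpha focal balance factor (> 0).
#' @param gamma focal focusing exponent (>= 0); `gamma = 0`, `alpha = 1`
#'   reduces the focal term to plain cross-entropy.
#' @return a `loss_config` list.
#' @export
loss_config <- function(lambda = 0.5, alpha = 0.25, gamma = 2) {
  if (lambda < 0 || lambda > 1)
    abort_validation("lambda must lie in [0, 1]")
  if (alpha <= 0) abort_validation("alpha must be positive")
  if (gamma < 0) abort_validation("gamma must be nonnegative")
  structure(list(lambda = lambda, alpha = alpha, gamma = gamma),
            class = "loss_config")
}

true_class_prob <- function(p, y) {
  d <- dim(p)
  if (!is.matrix(y) || !identical(dim(y), d[1:2]))
    abort_validation("probability map and mask have mismatched spatial sizes")
  yv <- as.integer(y)
  if (any(yv < 0L) || any(yv >= d[3]))
    abort_validation(sprintf("mask labels must lie in 0..%d", d[3] - 1L))
  pm <- matrix(p, d[1] * d[2], d[3])
  pmin(pmax(pm[cbind(seq_len(nrow(pm)), yv + 1L)], LOSS_EPS), 1 - LOSS_EPS)
}

#' Mean per-pixel cross-entropy loss
#'
#' @param p `[H, W, K]` probability array (per-pixel class distributions).
#' @param y integer `[H, W]` mask with labels in `0..K-1`.
#' @return scalar mean of `-log p(true class)` over pixels.
#' @export
cross_entropy_loss <- function(p, y) {
  mean(-log(true_class_prob(p, y)))
}

#' Mean per-pixel focal loss
#'
#' `alpha * (1 - p_t)^gamma * (-log p_t)` averaged over pixels, where `p_t`
#' is the probability assigned to the true class.
#'
#' @inheritParams cross_entropy_loss
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
focal_loss <- function(p, y, cfg = loss_config()) {
  pt <- true_class_prob(p, y)
  mean(cfg$alpha * (1 - pt)^cfg$gamma * (-log(pt)))
}

#' Hybrid cross-entropy / focal loss
#'
#' @inheritParams focal_loss
#' @return scalar `lambda * CE + (1 - lambda) * FL`.
#' @export
hybrid_loss <- function(p, y, cfg = loss_config()) {
  cfg$lambda * cross_entropy_loss(p, y) +
    (1 - cfg$lambda) * focal_loss(p, y, cfg)
}

# loss and gradient w.r.t. logits, for training; uses log-sum-exp directly so
# the gradient is exact even where the softmax saturates (no probability
# clipping on this path)
hybrid_loss_grad <- function(logits, y, cfg) {
  d <- dim(logits)
  n <- d[1] * d[2]
  zm <- matrix(logits, n, d[3])
  mx <- zm[cbind(seq_len(n), max.col(zm, ties.method = "first"))]
  zs <- zm - mx
  ez <- exp(zs)
  se <- rowSums(ez)
  p <- ez / se
  yv <- as.integer(y)
  if (any(yv < 0L) || any(yv >= d[3]))
    abort_validation(sprintf("mask labels must lie in 0..%d", d[3] - 1L))
  ti <- cbind(seq_len(n), yv + 1L)
  logpt <- zs[ti] - log(se)                       # finite for finite logits
  pt <- p[ti]
  u <- 1 - pt
  ce <- mean(-logpt)
  fl <- mean(cfg$alpha * u^cfg$gamma * (-logpt))
  loss <- cfg$lambda * ce + (1 - cfg$lambda) * fl
  onehot_sub <- p
  onehot_sub[ti] <- onehot_sub[ti] - 1            # p - onehot
  dce <- onehot_sub / n
  # focal: dL/dz_k = alpha [gamma u^(gamma-1) pt log pt - u^gamma] (delta - p_k) / n
  ug1 <- if (cfg$gamma >= 1) u^(cfg$gamma - 1) else (pmax(u, LOSS_EPS))^(cfg$gamma - 1)
  A <- cfg$alpha * (cfg$gamma * ug1 * pt * logpt - u^cfg$gamma) / n
  delta_minus_p <- -p
  delta_minus_p[ti] <- delta_minus_p[ti] + 1
  dfl <- A * delta_minus_p
  dz <- cfg$lambda * dce + (1 - cfg$lambda) * dfl
  list(loss = loss, dlogits = array(dz, d), ce = ce, fl = fl)
}
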