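#' Dice loss
#'
#' The soft Dice loss used to train the segmentation models under extreme
#' class imbalance:
#' \deqn{L = 1 - \frac{2\sum_i p_i g_i + \epsilon}{\sum_i p_i + \sum_i g_i + \epsilon}}
#' where \eqn{p_i} is the predicted foreground probability of pixel i,
#' \eqn{g_i} its binary label, and \eqn{\epsilon} a small smoothing constant
#' guarding against an empty denominator. For a batch
#' (\code{[H,W,1,N]} arrays) the loss is computed per image and averaged —
#' this preserves the per-sample imbalance semantics rather than pooling
#' pixels across the batch.
#'
#' @param pred Probabilities in \code{[0,1]}: a matrix or an
#'   \code{[H,W,1,N]} array.
#' @param truth Binary labels of the same shape.
#' @param eps Smoothing constant in \code{(0, 1]} (default \code{1e-6}).
#' @return A scalar loss in \code{[0, 1)}.
#' @export
#' @examples
#' dice_loss(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1), eps = 1e-12)
dice_loss <- function(pred, truth, eps = 1e-6) {
  check_pair(pred, truth)
  if (eps <= 0 || eps > 1) stop("eps must be in (0, 1]", call. = FALSE)
  mean(vapply(split_batch(pred, truth), function(pg) {
    num <- 2 * sum(pg$p * pg$g) + eps
    den <- sum(pg$p) + sum(pg$g) + eps
    1 - num / den
  }, numeric(1)))
}

# Gradient of the per-image-averaged Dice loss w.r.t. pred (same shape).
dice_loss_grad <- function(pred, truth, eps = 1e-6) {
  ps <- split_batch(pred, truth)
  n <- length(ps)
  g <- lapply(ps, function(pg) {
    num <- 2 * sum(pg$p * pg$g) + eps
    den <- sum(pg$p) + sum(pg$g) + eps
    (num / den^2 - 2 * pg$g / den) / n
  })
  rebuild_batch(g, pred)
}

#' Binary cross-entropy loss
#'
#' Pixel-mean of \eqn{-[g \log p + (1-g)\log(1-p)]}, with probabilities
#' clamped to \code{[clamp, 1-clamp]} before the logarithms. Serves as the
#' comparator loss to the Dice loss.
#'
#' @inheritParams dice_loss
#' @param clamp Positive clamping constant (default \code{1e-7}).
#' @return A scalar loss (\eqn{\log 2} for a uniform 0.5 prediction).
#' @export
bce_loss <- function(pred, truth, clamp = 1e-7) {
  check_pair(pred, truth)
  p <- pmin(pmax(pred, clamp), 1 - clamp)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

bce_loss_grad <- function(pred, truth, clamp = 1e-7) {
  p <- pmin(pmax(pred, clamp), 1 - clamp)
  g <- (-truth / p + (1 - truth) / (1 - p)) / length(pred)
  array(g, dim = dim(pred))
}

check_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) ||
      (is.null(dim(pred)) && length(pred) != length(truth)))
    stop("pred and truth must have identical shapes", call. = FALSE)
  invisible(NULL)
}

# Split a matrix or [H,W,1,N] array into per-image p/g pairs.
split_batch <- function(pred, truth) {
  d <- dim(pred)
  if (length(d) == 4) {
    lapply(seq_len(d[4]), function(n)
      list(p = pred[, , , n], g = truth[, , , n]))
  } else {
    list(list(p = pred, g = truth))
  }
}

rebuild_batch <- function(grads, pred) {
  d <- dim(pred)
  if (length(d) == 4) {
    out <- array(0, dim = d)
    for (n in seq_along(grads)) out[, , , n] <- grads[[n]]
    out
  } else {
    array(grads[[1]], dim = d)
  }
}
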