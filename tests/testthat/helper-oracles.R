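# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: metrics are recomputed with explicit pixel-set
# arithmetic, distances with exhaustive double loops, and convolutions with
# naive nested loops.

random_mask <- function(h, w, p = 0.3, nonempty = TRUE) {
  repeat {
    m <- matrix(rbinom(h * w, 1, p), h, w)
    if (!nonempty || sum(m) > 0) return(m)
  }
}

# Set-arithmetic metric oracle on binary masks.
oracle_metrics <- function(pred, truth) {
  P <- which(pred != 0)
  G <- which(truth != 0)
  tp <- length(intersect(P, G))
  fp <- length(setdiff(P, G))
  fn <- length(setdiff(G, P))
  jsc <- tp / length(union(P, G))
  list(
    tp = tp, fp = fp, fn = fn,
    tn = length(pred) - length(union(P, G)),
    dsc = 2 * tp / (length(P) + length(G)),
    jsc = jsc,
    ppv = if (length(P) == 0) 0 else tp / length(P),
    se = tp / length(G),
    rvd = abs(length(P) - length(G)) / length(G),
    voe = 1 - jsc
  )
}

# Exhaustive all-pairs Hausdorff distance.
oracle_hausdorff <- function(a, b) {
  pa <- which(a != 0, arr.ind = TRUE)
  pb <- which(b != 0, arr.ind = TRUE)
  dmat <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Naive same-padded 2D convolution for one [H,W,Ci] input and [k,k,Ci,Co]
# weights.
oracle_conv <- function(x, W, b) {
  k <- dim(W)[1]; p <- k %/% 2
  H <- dim(x)[1]; Wd <- dim(x)[2]; Ci <- dim(x)[3]; Co <- dim(W)[4]
  y <- array(0, dim = c(H, Wd, Co))
  for (co in seq_len(Co)) {
    y[, , co] <- b[co]
    for (ci in seq_len(Ci)) for (di in seq_len(k)) for (dj in seq_len(k)) {
      for (i in seq_len(H)) for (j in seq_len(Wd)) {
        si <- i + di - 1 - p; sj <- j + dj - 1 - p
        if (si >= 1 && si <= H && sj >= 1 && sj <= Wd)
          y[i, j, co] <- y[i, j, co] + x[si, sj, ci] * W[di, dj, ci, co]
      }
    }
  }
  y
}

# Flood fill connected-component count (8-connectivity) of a binary mask.
n_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- 0L
  for (i0 in seq_len(nrow(m))) for (j0 in seq_len(ncol(m))) {
    if (m[i0, j0] != 0 && lab[i0, j0] == 0L) {
      comp <- comp + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- comp
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          i <- p[1] + di; j <- p[2] + dj
          if (i >= 1 && i <= nrow(m) && j >= 1 && j <= ncol(m) &&
              m[i, j] != 0 && lab[i, j] == 0L) {
            lab[i, j] <- comp
            queue <- c(queue, list(c(i, j)))
          }
        }
      }
    }
  }
  comp
}

# Tiny architecture used to keep engine/workflow tests fast.
tiny_spec <- function(variant = "unet", ...) {
  architecture_spec(variant, input_size = c(16L, 16L), depth = 3L,
                    channel_schedule = c(4L, 8L, 16L), n_mca_blocks = 2L,
                    attention_reduction = 4L, ...)
}

tiny_samples <- function(n, size = 32L, seed = 9L) {
  # a 32x32 grid cannot hold the clinical 0.55% imbalance (under 8 pixels),
  # so the tiny fixtures use a 1% foreground target
  phantom_dataset(n, phantom_spec(size = c(size, size), seed = seed,
                                  fg_fraction_target = 0.01))
}
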