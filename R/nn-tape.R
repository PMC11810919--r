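# Reverse-mode tape over 4D feature maps [H, W, C, N].
#
# Each forward op appends a record (op name, input node ids, cached extras);
# tape_backward() replays the records in reverse, accumulating gradients for
# every node and for every named parameter touched. Parameters live in a
# plain named list (one entry per layer: $W/$b for convolutions and dense
# layers, $gamma/$beta for batch norm); batch-norm running statistics live in
# an environment so that forward passes in training mode can update them
# in place.

tape_new <- function(params, state = NULL, training = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$recs <- list()
  tp$params <- params
  tp$state <- if (is.null(state)) new.env(parent = emptyenv()) else state
  tp$training <- training
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, op, ins = integer(0), extra = NULL) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- value
  tp$recs[[tp$n]] <- list(op = op, ins = ins, extra = extra)
  tp$n
}

tp_value <- function(tp, id) { force(id); tp$vals[[id]] }

tp_input <- function(tp, x) tp_push(tp, x, "input")

tp_conv <- function(tp, id, pname) {
  force(id)
  p <- tp$params[[pname]]
  y <- conv2d_fw_cpp(tp$vals[[id]], p$W, p$b)
  tp_push(tp, y, "conv", id, list(pname = pname))
}

tp_tconv <- function(tp, id, pname) {
  force(id)
  p <- tp$params[[pname]]
  y <- tconv2_fw_cpp(tp$vals[[id]], p$W, p$b)
  tp_push(tp, y, "tconv", id, list(pname = pname))
}

tp_relu <- function(tp, id) {
  force(id)
  x <- tp$vals[[id]]
  y <- x
  y[y < 0] <- 0
  tp_push(tp, y, "relu", id)
}

tp_sigmoid <- function(tp, id) {
  force(id)
  y <- 1 / (1 + exp(-tp$vals[[id]]))
  tp_push(tp, y, "sigmoid", id)
}

tp_maxpool <- function(tp, id) {
  force(id)
  r <- maxpool2_fw_cpp(tp$vals[[id]])
  d <- dim(tp$vals[[id]])
  tp_push(tp, r$y, "maxpool", id, list(idx = r$idx, H = d[1], W = d[2]))
}

tp_avgpool <- function(tp, id, f) {
  force(id)
  d <- dim(tp$vals[[id]])
  y <- avgpool_fw_cpp(tp$vals[[id]], as.integer(f))
  tp_push(tp, y, "avgpool", id, list(f = as.integer(f), H = d[1], W = d[2]))
}

# Global average pool: [H,W,C,N] -> [C,N].
tp_gap <- function(tp, id) {
  force(id)
  x <- tp$vals[[id]]
  d <- dim(x)
  y <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
  tp_push(tp, y, "gap", id, list(dims = d))
}

# Dense layer on [C,N] descriptors.
tp_dense <- function(tp, id, pname) {
  force(id)
  p <- tp$params[[pname]]
  y <- p$W %*% tp$vals[[id]] + p$b
  tp_push(tp, y, "dense", id, list(pname = pname))
}

# Channel concatenation of two or more [H,W,*,N] maps.
tp_concat <- function(tp, ids) {
  force(ids)
  xs <- lapply(ids, function(i) tp$vals[[i]])
  ds <- lapply(xs, dim)
  cs <- vapply(ds, `[`, integer(1), 3L)
  d1 <- ds[[1]]
  y <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (k in seq_along(xs)) {
    y[, , at + seq_len(cs[k]), ] <- xs[[k]]
    at <- at + cs[k]
  }
  tp_push(tp, y, "concat", as.integer(ids), list(cs = cs))
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] + tp$vals[[b]], "add", c(a, b))
}

# Elementwise mean of same-shaped [C,N] descriptor nodes.
tp_mean <- function(tp, ids) {
  force(ids)
  xs <- lapply(ids, function(i) tp$vals[[i]])
  tp_push(tp, Reduce(`+`, xs) / length(xs), "mean", as.integer(ids))
}

# Elementwise sum of same-shaped [C,N] descriptor nodes.
tp_sum <- function(tp, ids) {
  force(ids)
  xs <- lapply(ids, function(i) tp$vals[[i]])
  tp_push(tp, Reduce(`+`, xs), "sum", as.integer(ids))
}

# Row concatenation of [C,N] descriptor nodes (for descriptor_combine = "concat").
tp_rbind <- function(tp, ids) {
  force(ids)
  xs <- lapply(ids, function(i) tp$vals[[i]])
  rs <- vapply(xs, nrow, integer(1))
  tp_push(tp, do.call(rbind, xs), "rbind", as.integer(ids), list(rs = rs))
}

# Multiply feature map [H,W,C,N] by per-channel gates [C,N].
tp_scale_channels <- function(tp, id, gid) {
  force(id); force(gid)
  x <- tp$vals[[id]]
  g <- tp$vals[[gid]]
  d <- dim(x)
  garr <- array(rep(g, each = d[1] * d[2]), dim = d)
  tp_push(tp, x * garr, "scale", c(id, gid), list(dims = d))
}

# Constant node (no gradient flows into it).
tp_const <- function(tp, x) tp_push(tp, x, "const")

# Batch normalization over (H, W, N) per channel. Training mode uses batch
# statistics and updates exponential running statistics in tp$state;
# inference mode normalizes with the stored running statistics.
tp_bn <- function(tp, id, pname, eps = 1e-5, momentum = 0.9) {
  force(id)
  p <- tp$params[[pname]]
  x <- tp$vals[[id]]
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C) # rows: (h,w,n), cols: channel
  st <- tp$state[[pname]]
  if (is.null(st)) st <- list(mean = rep(0, C), var = rep(1, C))
  if (tp$training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    tp$state[[pname]] <- list(mean = momentum * st$mean + (1 - momentum) * mu,
                              var = momentum * st$var + (1 - momentum) * va)
  } else {
    mu <- st$mean
    va <- st$var
  }
  inv <- 1 / sqrt(va + eps)
  xh <- sweep(sweep(xm, 2, mu, "-"), 2, inv, "*")
  ym <- sweep(sweep(xh, 2, p$gamma, "*"), 2, p$beta, "+")
  y <- aperm(array(ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  tp_push(tp, y, "bn", id,
          list(pname = pname, xh = xh, inv = inv, dims = d))
}

# Backpropagate d(loss)/d(out_value) from node `out` to every parameter.
# Returns a named list of parameter gradients mirroring tp$params.
tape_backward <- function(tp, out, dout) {
  adj <- vector("list", tp$n)
  adj[[out]] <- dout
  pg <- list()
  add_pg <- function(pname, field, g) {
    if (is.null(pg[[pname]])) pg[[pname]] <<- list()
    cur <- pg[[pname]][[field]]
    pg[[pname]][[field]] <<- if (is.null(cur)) g else cur + g
  }
  acc <- function(i, g) {
    adj[[i]] <<- if (is.null(adj[[i]])) g else adj[[i]] + g
  }
  for (k in seq(tp$n, 1L)) {
    dy <- adj[[k]]
    if (is.null(dy)) next
    r <- tp$recs[[k]]
    switch(r$op,
      input = NULL,
      const = NULL,
      conv = {
        p <- tp$params[[r$extra$pname]]
        g <- conv2d_bw_cpp(tp$vals[[r$ins]], p$W, dy)
        add_pg(r$extra$pname, "W", g$dW)
        add_pg(r$extra$pname, "b", g$db)
        acc(r$ins, g$dx)
      },
      tconv = {
        p <- tp$params[[r$extra$pname]]
        g <- tconv2_bw_cpp(tp$vals[[r$ins]], p$W, dy)
        add_pg(r$extra$pname, "W", g$dW)
        add_pg(r$extra$pname, "b", g$db)
        acc(r$ins, g$dx)
      },
      relu = {
        dx <- dy
        dx[tp$vals[[r$ins]] <= 0] <- 0
        acc(r$ins, dx)
      },
      sigmoid = {
        y <- tp$vals[[k]]
        acc(r$ins, dy * y * (1 - y))
      },
      maxpool = acc(r$ins, maxpool2_bw_cpp(dy, r$extra$idx, r$extra$H, r$extra$W)),
      avgpool = acc(r$ins, avgpool_bw_cpp(dy, r$extra$f, r$extra$H, r$extra$W)),
      gap = {
        d <- r$extra$dims
        acc(r$ins, array(rep(dy / (d[1] * d[2]), each = d[1] * d[2]), dim = d))
      },
      dense = {
        p <- tp$params[[r$extra$pname]]
        x <- tp$vals[[r$ins]]
        add_pg(r$extra$pname, "W", dy %*% t(x))
        add_pg(r$extra$pname, "b", rowSums(dy))
        acc(r$ins, t(p$W) %*% dy)
      },
      concat = {
        cs <- r$extra$cs
        at <- 0L
        for (j in seq_along(r$ins)) {
          acc(r$ins[j], dy[, , at + seq_len(cs[j]), , drop = FALSE])
          at <- at + cs[j]
        }
      },
      add = {
        acc(r$ins[1], dy)
        acc(r$ins[2], dy)
      },
      mean = {
        g <- dy / length(r$ins)
        for (i in r$ins) acc(i, g)
      },
      sum = {
        for (i in r$ins) acc(i, dy)
      },
      rbind = {
        rs <- r$extra$rs
        at <- 0L
        for (j in seq_along(r$ins)) {
          acc(r$ins[j], dy[at + seq_len(rs[j]), , drop = FALSE])
          at <- at + rs[j]
        }
      },
      scale = {
        d <- r$extra$dims
        x <- tp$vals[[r$ins[1]]]
        g <- tp$vals[[r$ins[2]]]
        garr <- array(rep(g, each = d[1] * d[2]), dim = d)
        acc(r$ins[1], dy * garr)
        dg <- matrix(colSums(matrix(dy * x, nrow = d[1] * d[2])), nrow = d[3])
        acc(r$ins[2], dg)
      },
      bn = {
        e <- r$extra
        p <- tp$params[[e$pname]]
        d <- e$dims
        C <- d[3]
        m <- d[1] * d[2] * d[4]
        dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
        add_pg(e$pname, "gamma", colSums(dym * e$xh))
        add_pg(e$pname, "beta", colSums(dym))
        if (tp$training) {
          dxh <- sweep(dym, 2, p$gamma, "*")
          s1 <- colSums(dxh)
          s2 <- colSums(dxh * e$xh)
          dxm <- sweep(dxh - matrix(s1 / m, m, C, byrow = TRUE) -
                         e$xh * matrix(s2 / m, m, C, byrow = TRUE),
                       2, e$inv, "*")
        } else {
          dxm <- sweep(sweep(dym, 2, p$gamma, "*"), 2, e$inv, "*")
        }
        dx <- aperm(array(dxm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
        acc(r$ins, dx)
      },
      stop("unknown op in tape: ", r$op)
    )
  }
  pg
}
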