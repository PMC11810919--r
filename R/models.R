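#' Architecture specification for the segmentation model family
#'
#' Describes one member of the U-Net family used for gallbladder
#' segmentation: the plain U-Net baseline, SEU-Net (U-Net with
#' squeeze-and-excitation channel attention after every encoder stage), and
#' MCAU-Net (U-Net whose first \code{n_mca_blocks} encoder stages are
#' replaced by multi-scale channel attention blocks, with a batch-normalized
#' residual decoder).
#'
#' @param variant One of \code{"unet"}, \code{"seunet"}, \code{"mcau"}.
#' @param input_size Integer pair, spatial size of the input slices. Must be
#'   divisible by \code{2^(depth-1)}.
#' @param input_channels Number of input channels (1 for grayscale CT).
#' @param depth Number of encoder stages including the bottleneck.
#' @param channel_schedule Integer vector of length \code{depth}; must double
#'   at every stage. The default \code{16,32,64,128,256} is the pinned
#'   baseline configuration.
#' @param n_mca_blocks Number of encoder stages (shallowest first) replaced
#'   by MCA blocks; only used by the \code{"mcau"} variant.
#' @param kernel_set Three odd, strictly increasing kernel sizes for the
#'   multi-scale feature extraction branch; \code{c(3,5,7)} or \code{c(5,7,9)}.
#' @param pooling_factors Average-pooling factors used to build the
#'   multi-scale channel descriptors (default 2 and 4).
#' @param attention_reduction Bottleneck reduction ratio r of the channel
#'   excitation (C -> C/r -> C).
#' @param descriptor_combine How the per-scale global descriptors are merged
#'   before excitation: \code{"mean"} (default), \code{"sum"} or
#'   \code{"concat"}.
#' @param enable_multiscale_conv,enable_channel_attention Ablation switches
#'   for the two halves of the MCA block. With both disabled an MCA stage
#'   reduces to the baseline pair of 3x3 convolutions.
#'
#' @return An object of class \code{gb_arch_spec}.
#' @export
architecture_spec <- function(variant = c("unet", "seunet", "mcau"),
                              input_size = c(64L, 64L),
                              input_channels = 1L,
                              depth = 5L,
                              channel_schedule = c(16L, 32L, 64L, 128L, 256L),
                              n_mca_blocks = 2L,
                              kernel_set = c(3L, 5L, 7L),
                              pooling_factors = c(2L, 4L),
                              attention_reduction = 4L,
                              descriptor_combine = c("mean", "sum", "concat"),
                              enable_multiscale_conv = TRUE,
                              enable_channel_attention = TRUE) {
  variant <- match.arg(variant)
  descriptor_combine <- match.arg(descriptor_combine)
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  channel_schedule <- as.integer(channel_schedule)
  kernel_set <- as.integer(kernel_set)
  if (length(channel_schedule) != depth)
    stop("channel_schedule must have one entry per stage", call. = FALSE)
  if (depth >= 2 && any(channel_schedule[-1] != 2L * channel_schedule[-depth]))
    stop("channel_schedule must double at every stage", call. = FALSE)
  if (length(kernel_set) != 3 || any(kernel_set %% 2 == 0) ||
      any(diff(kernel_set) <= 0))
    stop("kernel_set must be three odd, strictly increasing sizes", call. = FALSE)
  if (any(input_size %% 2^(depth - 1) != 0))
    stop("input_size must be divisible by 2^(depth-1)", call. = FALSE)
  if (variant == "mcau" && (n_mca_blocks < 1 || n_mca_blocks > depth - 1))
    stop("n_mca_blocks must be between 1 and depth-1", call. = FALSE)
  structure(list(
    variant = variant, input_size = input_size,
    input_channels = as.integer(input_channels), depth = depth,
    channel_schedule = channel_schedule,
    n_mca_blocks = as.integer(n_mca_blocks), kernel_set = kernel_set,
    pooling_factors = as.integer(pooling_factors),
    attention_reduction = as.integer(attention_reduction),
    descriptor_combine = descriptor_combine,
    enable_multiscale_conv = isTRUE(enable_multiscale_conv),
    enable_channel_attention = isTRUE(enable_channel_attention)
  ), class = "gb_arch_spec")
}

#' @export
print.gb_arch_spec <- function(x, ...) {
  cat(sprintf("<gb_arch_spec: %s, depth %d, channels %s>\n", x$variant,
              x$depth, paste(x$channel_schedule, collapse = "/")))
  if (x$variant == "mcau")
    cat(sprintf("  MCA blocks: %d (kernels %s), attention r=%d, combine=%s\n",
                x$n_mca_blocks, paste(x$kernel_set, collapse = "/"),
                x$attention_reduction, x$descriptor_combine))
  invisible(x)
}

## ---- parameter initialisation -------------------------------------------

he_conv <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  list(W = array(stats::rnorm(k * k * cin * cout, 0, sd), dim = c(k, k, cin, cout)),
       b = rep(0, cout))
}

he_dense <- function(cin, cout) {
  sd <- sqrt(2 / cin)
  list(W = matrix(stats::rnorm(cout * cin, 0, sd), cout, cin), b = rep(0, cout))
}

bn_params <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

## ---- block constructors --------------------------------------------------

#' Squeeze-and-excitation (cSE) channel attention block
#'
#' Global average pooling followed by a two-layer excitation
#' (C -> C/r with ReLU, C/r -> C with sigmoid) whose output gates the
#' channels of the input feature map.
#'
#' @param channels Number of feature channels C.
#' @param reduction Bottleneck reduction r; \code{channels} must be divisible
#'   by it.
#' @return A block constructor: a list with \code{init(prefix)} returning the
#'   parameter template, \code{forward(tp, id, prefix, force_gates)} applying
#'   the block on a tape, and \code{n_params}, the closed-form parameter
#'   count \eqn{2C^2/r + C + C/r}.
#' @export
cse_block <- function(channels, reduction) {
  if (channels %% reduction != 0)
    stop("channels must be divisible by reduction", call. = FALSE)
  cr <- channels %/% reduction
  list(
    channels = channels, reduction = reduction,
    n_params = 2 * channels^2 / reduction + channels + cr,
    init = function(prefix) {
      stats::setNames(list(he_dense(channels, cr), he_dense(cr, channels)),
                      paste0(prefix, c("_fc1", "_fc2")))
    },
    forward = function(tp, id, prefix, force_gates = NULL) {
      g <- tp_gap(tp, id)
      g <- tp_relu(tp, tp_dense(tp, g, paste0(prefix, "_fc1")))
      g <- tp_sigmoid(tp, tp_dense(tp, g, paste0(prefix, "_fc2")))
      if (!is.null(force_gates)) {
        d <- dim(tp_value(tp, g))
        g <- tp_const(tp, matrix(force_gates, d[1], d[2]))
      }
      tp_scale_channels(tp, id, g)
    }
  )
}

#' Multi-scale channel attention (MCA) block
#'
#' The block that replaces the two encoder convolutions of a stage. Part A
#' (multi-scale feature extraction) runs three parallel same-padded
#' convolutions with the spec's kernel sizes, concatenates the 3C channels
#' and restores C channels with a 1x1 convolution. Part B (multi-scale
#' channel attention) average-pools Part A's output at the spec's pooling
#' factors, takes global average descriptors of the original and pooled
#' maps, merges them (\code{descriptor_combine}), and passes the merged
#' descriptor through a cSE excitation whose sigmoid gates re-weight Part A's
#' channels. Either part can be disabled (ablation); with both disabled the
#' block is the baseline pair of 3x3 convolutions.
#'
#' @param in_channels,channels Input and output channel counts.
#' @param spec An \code{\link{architecture_spec}} carrying the kernel set,
#'   pooling factors, reduction and combine rule.
#' @return A block constructor list (see \code{\link{cse_block}}).
#' @export
mca_block <- function(in_channels, channels, spec) {
  r <- spec$attention_reduction
  if (channels < r) stop("channels must be at least the reduction", call. = FALSE)
  cr <- max(1L, channels %/% r)
  desc_in <- if (spec$descriptor_combine == "concat") 3L * channels else channels
  init <- function(prefix) {
    p <- list()
    if (spec$enable_multiscale_conv) {
      for (k in spec$kernel_set)
        p[[paste0(prefix, "_ms", k)]] <- he_conv(k, in_channels, channels)
      p[[paste0(prefix, "_fuse")]] <- he_conv(1, 3 * channels, channels)
    } else {
      p[[paste0(prefix, "_conv1")]] <- he_conv(3, in_channels, channels)
      p[[paste0(prefix, "_conv2")]] <- he_conv(3, channels, channels)
    }
    if (spec$enable_channel_attention) {
      p[[paste0(prefix, "_att_fc1")]] <- he_dense(desc_in, cr)
      p[[paste0(prefix, "_att_fc2")]] <- he_dense(cr, channels)
    }
    p
  }
  forward <- function(tp, id, prefix, force_gates = NULL) {
    if (spec$enable_multiscale_conv) {
      branches <- vapply(spec$kernel_set, function(k) {
        tp_relu(tp, tp_conv(tp, id, paste0(prefix, "_ms", k)))
      }, integer(1))
      v <- tp_concat(tp, branches)
      v <- tp_relu(tp, tp_conv(tp, v, paste0(prefix, "_fuse")))
    } else {
      v <- tp_relu(tp, tp_conv(tp, id, paste0(prefix, "_conv1")))
      v <- tp_relu(tp, tp_conv(tp, v, paste0(prefix, "_conv2")))
    }
    if (spec$enable_channel_attention) {
      pooled <- lapply(spec$pooling_factors, function(f) tp_avgpool(tp, v, f))
      descs <- c(tp_gap(tp, v), vapply(pooled, function(p) tp_gap(tp, p), integer(1)))
      d <- switch(spec$descriptor_combine,
                  mean = tp_mean(tp, descs),
                  sum = tp_sum(tp, descs),
                  concat = tp_rbind(tp, descs))
      g <- tp_relu(tp, tp_dense(tp, d, paste0(prefix, "_att_fc1")))
      g <- tp_sigmoid(tp, tp_dense(tp, g, paste0(prefix, "_att_fc2")))
      if (!is.null(force_gates)) {
        dm <- dim(tp_value(tp, g))
        g <- tp_const(tp, matrix(force_gates, dm[1], dm[2]))
      }
      v <- tp_scale_channels(tp, v, g)
    }
    v
  }
  list(in_channels = in_channels, channels = channels,
       init = init, forward = forward)
}

## ---- model builders ------------------------------------------------------

build_params <- function(spec) {
  d <- spec$depth
  ch <- spec$channel_schedule
  p <- list()
  for (s in seq_len(d)) {
    cin <- if (s == 1) spec$input_channels else ch[s - 1]
    use_mca <- spec$variant == "mcau" && s <= spec$n_mca_blocks
    if (use_mca) {
      p <- c(p, mca_block(cin, ch[s], spec)$init(paste0("enc", s)))
    } else {
      p[[paste0("enc", s, "_conv1")]] <- he_conv(3, cin, ch[s])
      p[[paste0("enc", s, "_conv2")]] <- he_conv(3, ch[s], ch[s])
      if (spec$variant == "seunet")
        p <- c(p, cse_block(ch[s], spec$attention_reduction)$init(paste0("enc", s, "_se")))
    }
  }
  for (s in seq(d - 1, 1)) {
    p[[paste0("up", s)]] <- he_conv(2, ch[s + 1], ch[s])
    p[[paste0("dec", s, "_conv1")]] <- he_conv(3, 2 * ch[s], ch[s])
    p[[paste0("dec", s, "_conv2")]] <- he_conv(3, ch[s], ch[s])
    if (spec$variant == "mcau") {
      p[[paste0("dec", s, "_bn1")]] <- bn_params(ch[s])
      p[[paste0("dec", s, "_bn2")]] <- bn_params(ch[s])
      p[[paste0("dec", s, "_proj")]] <- he_conv(1, 2 * ch[s], ch[s])
    }
  }
  p[["out"]] <- he_conv(1, ch[1], 1)
  p
}

#' Build a segmentation model
#'
#' Instantiates the network described by an \code{\link{architecture_spec}}
#' with freshly initialised weights (He initialisation, drawn from R's
#' current random stream — seed it for reproducible builds).
#'
#' @param spec An \code{\link{architecture_spec}}.
#' @return An object of class \code{gb_model}.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "gb_arch_spec"))
  params <- build_params(spec)
  state <- new.env(parent = emptyenv())
  for (nm in names(params)) {
    if (!is.null(params[[nm]]$gamma)) {
      c_ <- length(params[[nm]]$gamma)
      state[[nm]] <- list(mean = rep(0, c_), var = rep(1, c_))
    }
  }
  structure(list(spec = spec, params = params, state = state),
            class = "gb_model")
}

#' @rdname build_model
#' @export
build_unet <- function(spec = architecture_spec("unet")) {
  stopifnot(spec$variant == "unet")
  build_model(spec)
}

#' @rdname build_model
#' @export
build_seunet <- function(spec = architecture_spec("seunet")) {
  stopifnot(spec$variant == "seunet")
  build_model(spec)
}

#' @rdname build_model
#' @param n_blocks Convenience: number of MCA blocks for \code{build_mcau_net}
#'   when \code{spec} is not supplied.
#' @export
build_mcau_net <- function(n_blocks = 2L, spec = NULL) {
  if (is.null(spec)) spec <- architecture_spec("mcau", n_mca_blocks = n_blocks)
  stopifnot(spec$variant == "mcau")
  build_model(spec)
}

# Forward pass on a tape. Returns list(tape, out): `out` is the node id of
# the sigmoid probability map.
gb_forward <- function(model, x, training = FALSE, force_gates = NULL) {
  spec <- model$spec
  tp <- tape_new(model$params, model$state, training = training)
  v <- tp_input(tp, x)
  skips <- integer(spec$depth - 1)
  for (s in seq_len(spec$depth)) {
    use_mca <- spec$variant == "mcau" && s <= spec$n_mca_blocks
    if (use_mca) {
      cin <- if (s == 1) spec$input_channels else spec$channel_schedule[s - 1]
      blk <- mca_block(cin, spec$channel_schedule[s], spec)
      v <- blk$forward(tp, v, paste0("enc", s), force_gates)
    } else {
      v <- tp_relu(tp, tp_conv(tp, v, paste0("enc", s, "_conv1")))
      v <- tp_relu(tp, tp_conv(tp, v, paste0("enc", s, "_conv2")))
      if (spec$variant == "seunet") {
        blk <- cse_block(spec$channel_schedule[s], spec$attention_reduction)
        v <- blk$forward(tp, v, paste0("enc", s, "_se"), force_gates)
      }
    }
    if (s < spec$depth) {
      skips[s] <- v
      v <- tp_maxpool(tp, v)
    }
  }
  for (s in seq(spec$depth - 1, 1)) {
    v <- tp_tconv(tp, v, paste0("up", s))
    v <- tp_concat(tp, c(v, skips[s]))
    if (spec$variant == "mcau") {
      h <- tp_relu(tp, tp_bn(tp, tp_conv(tp, v, paste0("dec", s, "_conv1")),
                             paste0("dec", s, "_bn1")))
      h <- tp_bn(tp, tp_conv(tp, h, paste0("dec", s, "_conv2")),
                 paste0("dec", s, "_bn2"))
      sc <- tp_conv(tp, v, paste0("dec", s, "_proj"))
      v <- tp_relu(tp, tp_add(tp, h, sc))
    } else {
      v <- tp_relu(tp, tp_conv(tp, v, paste0("dec", s, "_conv1")))
      v <- tp_relu(tp, tp_conv(tp, v, paste0("dec", s, "_conv2")))
    }
  }
  out <- tp_sigmoid(tp, tp_conv(tp, v, "out"))
  list(tape = tp, out = out)
}

# Coerce an image / batch to the canonical [H,W,C,N] layout.
as_batch <- function(x, channels = 1L) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3) x <- array(x, dim = c(dim(x)[1:2], channels, dim(x)[3]))
  stopifnot(length(dim(x)) == 4)
  x
}

#' Predict foreground probabilities
#'
#' Runs the network in inference mode (batch-norm layers use their running
#' statistics) and returns per-pixel foreground probabilities.
#'
#' @param object A \code{gb_model}.
#' @param x A matrix (one slice), an \code{[H,W,N]} array, or an
#'   \code{[H,W,C,N]} array.
#' @param batch_size Samples per forward pass.
#' @param force_gates Optional constant overriding every attention gate
#'   (diagnostic; \code{force_gates = 1} disables attention re-weighting).
#' @param ... Unused.
#' @return An \code{[H,W,1,N]} array of probabilities in \code{[0,1]}.
#' @export
predict.gb_model <- function(object, x, batch_size = 8L, force_gates = NULL, ...) {
  x <- as_batch(x, object$spec$input_channels)
  n <- dim(x)[4]
  out <- array(0, dim = c(dim(x)[1:2], 1L, n))
  for (i in seq(1, n, by = batch_size)) {
    j <- min(i + batch_size - 1, n)
    fw <- gb_forward(object, x[, , , i:j, drop = FALSE],
                     training = FALSE, force_gates = force_gates)
    out[, , , i:j] <- tp_value(fw$tape, fw$out)
  }
  out
}

#' Count model parameters
#'
#' Exact parameter totals partitioned into trainable weights and
#' non-trainable state (batch-normalization running statistics).
#'
#' @param model A \code{gb_model}.
#' @return A tibble with columns \code{total}, \code{trainable},
#'   \code{non_trainable}.
#' @export
count_parameters <- function(model) {
  trainable <- sum(vapply(model$params, function(p)
    sum(vapply(p, length, integer(1))), numeric(1)))
  non_trainable <- sum(vapply(ls(model$state), function(nm)
    sum(lengths(model$state[[nm]])), numeric(1)))
  tibble::tibble(total = trainable + non_trainable,
                 trainable = trainable, non_trainable = non_trainable)
}

#' @export
print.gb_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<gb_model: %s | params %s (trainable %s, non-trainable %s)>\n",
              x$spec$variant, format(pc$total, big.mark = ","),
              format(pc$trainable, big.mark = ","),
              format(pc$non_trainable, big.mark = ",")))
  invisible(x)
}
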