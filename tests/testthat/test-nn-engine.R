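# The network engine: convolution kernels against naive oracles, pooling
# routing, batch-norm statistics, and end-to-end gradient checks of the
# reverse-mode tape.

test_that("same-padded convolution matches a naive nested-loop oracle", {
  set.seed(51)
  for (k in c(1L, 3L, 5L)) {
    x <- array(rnorm(7 * 6 * 3 * 2), dim = c(7, 6, 3, 2))
    W <- array(rnorm(k * k * 3 * 4), dim = c(k, k, 3, 4))
    b <- rnorm(4)
    y <- gbseg:::conv2d_fw_cpp(x, W, b)
    for (n in 1:2)
      expect_equal(y[, , , n], oracle_conv(x[, , , n], W, b), tolerance = 1e-12)
  }
})

test_that("a single biased 3x3 convolution layer has 9*Cin*Cout + Cout parameters", {
  p <- gbseg:::he_conv(3, 1, 16)
  expect_equal(length(p$W) + length(p$b), 160)
})

test_that("transposed convolution upsamples by 2 and inverts shapes", {
  set.seed(52)
  x <- array(rnorm(4 * 4 * 2 * 1), dim = c(4, 4, 2, 1))
  W <- array(rnorm(2 * 2 * 2 * 3), dim = c(2, 2, 2, 3))
  b <- rnorm(3)
  y <- gbseg:::tconv2_fw_cpp(x, W, b)
  expect_identical(dim(y), c(8L, 8L, 3L, 1L))
  # non-overlapping stride-2 kernel: each output block is the weighted input
  expect_equal(y[1, 1, 1, 1], sum(x[1, 1, , 1] * W[1, 1, , 1]) + b[1],
               tolerance = 1e-12)
  expect_equal(y[2, 1, 2, 1], sum(x[1, 1, , 1] * W[2, 1, , 2]) + b[2],
               tolerance = 1e-12)
  expect_equal(y[8, 8, 3, 1], sum(x[4, 4, , 1] * W[2, 2, , 3]) + b[3],
               tolerance = 1e-12)
})

test_that("max pooling keeps window maxima and routes gradients to the argmax", {
  x <- array(0, dim = c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(c(1, 5, 2, 0,
                          3, 4, 8, 7,
                          0, 1, 2, 3,
                          9, 6, 4, 5), 4, 4, byrow = TRUE)
  r <- gbseg:::maxpool2_fw_cpp(x)
  expect_equal(r$y[, , 1, 1], matrix(c(5, 8, 9, 5), 2, 2, byrow = TRUE))
  dy <- array(1, dim = c(2, 2, 1, 1))
  dx <- gbseg:::maxpool2_bw_cpp(dy, r$idx, 4L, 4L)
  expect_equal(sum(dx), 4)
  expect_equal(dx[1, 2, 1, 1], 1) # the 5
  expect_equal(dx[2, 3, 1, 1], 1) # the 8
  expect_equal(dx[4, 1, 1, 1], 1) # the 9
  expect_equal(dx[4, 4, 1, 1], 1) # the 5
})

test_that("average pooling averages non-overlapping windows", {
  x <- array(seq_len(16), dim = c(4, 4, 1, 1))
  y2 <- gbseg:::avgpool_fw_cpp(x, 2L)
  expect_equal(y2[1, 1, 1, 1], mean(x[1:2, 1:2, 1, 1]))
  y4 <- gbseg:::avgpool_fw_cpp(x, 4L)
  expect_equal(y4[1, 1, 1, 1], mean(x))
  dx <- gbseg:::avgpool_bw_cpp(array(1, dim = c(1, 1, 1, 1)), 4L, 4L, 4L)
  expect_equal(dx[, , 1, 1], matrix(1 / 16, 4, 4))
})

test_that("batch norm standardizes per channel in training mode", {
  set.seed(53)
  params <- list(bn = list(gamma = c(2, 1), beta = c(0.5, -1)))
  tp <- gbseg:::tape_new(params, training = TRUE)
  x <- array(rnorm(8 * 8 * 2 * 3, mean = 3, sd = 2), dim = c(8, 8, 2, 3))
  v <- gbseg:::tp_input(tp, x)
  y <- gbseg:::tp_value(tp, gbseg:::tp_bn(tp, v, "bn"))
  for (c_ in 1:2) {
    vals <- as.vector(y[, , c_, ])
    expect_equal(mean(vals), params$bn$beta[c_], tolerance = 1e-6)
    expect_equal(sd(vals), params$bn$gamma[c_], tolerance = 1e-2)
  }
  # running statistics were updated away from their initial values
  expect_false(isTRUE(all.equal(tp$state$bn$mean, c(0, 0))))
})

test_that("tape gradients agree with finite differences for every variant", {
  set.seed(54)
  check_variant <- function(variant, combine = "mean") {
    m <- build_model(tiny_spec(variant, descriptor_combine = combine))
    x <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
    g <- array(rbinom(16 * 16 * 2, 1, 0.1), dim = c(16, 16, 1, 2))
    lossfun <- function(mm) {
      fw <- gbseg:::gb_forward(mm, x, training = TRUE)
      dice_loss(gbseg:::tp_value(fw$tape, fw$out), g)
    }
    fw <- gbseg:::gb_forward(m, x, training = TRUE)
    p <- gbseg:::tp_value(fw$tape, fw$out)
    grads <- gbseg:::tape_backward(fw$tape, fw$out,
                                  gbseg:::dice_loss_grad(p, g))
    nms <- sample(names(grads), min(6, length(grads)))
    for (nm in nms) {
      f <- names(grads[[nm]])[1]
      i <- sample(length(m$params[[nm]][[f]]), 1)
      m2 <- m; m2$params[[nm]][[f]][i] <- m2$params[[nm]][[f]][i] + 1e-6
      m3 <- m; m3$params[[nm]][[f]][i] <- m3$params[[nm]][[f]][i] - 1e-6
      num <- (lossfun(m2) - lossfun(m3)) / 2e-6
      ana <- grads[[nm]][[f]][i]
      # relative error with an absolute floor (finite differences lose
      # precision when the true gradient is ~1e-10)
      err <- abs(ana - num) / max(1e-7, abs(ana) + abs(num))
      expect_lt(err, 5e-3)
    }
  }
  check_variant("unet")
  check_variant("seunet")
  check_variant("mcau")
  check_variant("mcau", combine = "concat")
})
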