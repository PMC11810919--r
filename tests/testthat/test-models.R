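test_that("the pinned baseline U-Net reproduces the reference parameter count", {
  set.seed(61)
  m <- build_unet()
  pc <- count_parameters(m)
  expect_equal(pc$total, 1940817)
  expect_equal(pc$trainable, 1940817)
  expect_equal(pc$non_trainable, 0)
})

test_that("architecture specs validate their invariants", {
  expect_error(architecture_spec("unet", channel_schedule = c(16L, 30L, 64L, 128L, 256L)),
               "double")
  expect_error(architecture_spec("unet", kernel_set = c(3L, 4L, 7L)), "odd")
  expect_error(architecture_spec("unet", kernel_set = c(7L, 5L, 3L)), "increasing")
  expect_error(architecture_spec("unet", input_size = c(60L, 60L)), "divisible")
  expect_error(architecture_spec("mcau", n_mca_blocks = 5L), "between 1 and")
})

test_that("every variant preserves spatial shape and emits probabilities", {
  set.seed(62)
  x <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  for (variant in c("unet", "seunet", "mcau")) {
    m <- build_model(tiny_spec(variant))
    p <- predict(m, x)
    expect_identical(dim(p), c(16L, 16L, 1L, 2L))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("parameter count is independent of the input spatial size", {
  set.seed(63)
  a <- count_parameters(build_model(architecture_spec("mcau", input_size = c(32, 32))))
  b <- count_parameters(build_model(architecture_spec("mcau", input_size = c(64, 64))))
  expect_equal(a, b)
})

test_that("parameter counts are ordered across the model family", {
  set.seed(64)
  unet <- count_parameters(build_unet())$total
  seunet <- count_parameters(build_seunet())$total
  mcau <- lapply(1:3, function(nb) count_parameters(build_mcau_net(nb)))
  expect_gt(seunet, unet)
  for (pc in mcau) {
    expect_gt(pc$total, unet)
    expect_lt(pc$total, 103239195) # printed transformer-hybrid reference bound
    expect_gt(pc$non_trainable, 0) # batch-norm running statistics
    expect_equal(pc$total, pc$trainable + pc$non_trainable)
  }
  # non-decreasing in the number of MCA blocks
  totals <- vapply(mcau, function(pc) pc$total, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("larger kernel sets cost more parameters", {
  set.seed(65)
  small <- count_parameters(build_model(architecture_spec("mcau", kernel_set = c(3L, 5L, 7L))))
  large <- count_parameters(build_model(architecture_spec("mcau", kernel_set = c(5L, 7L, 9L))))
  expect_gt(large$total, small$total)
})

test_that("the cSE block matches its closed-form parameter count and gates in (0,1)", {
  blk <- cse_block(16, 4)
  params <- blk$init("se")
  built <- sum(vapply(params, function(p) sum(vapply(p, length, integer(1))), numeric(1)))
  expect_equal(built, blk$n_params)
  expect_equal(blk$n_params, 2 * 16^2 / 4 + 16 + 4)
  expect_error(cse_block(10, 4), "divisible")
  # gates strictly inside (0,1) on a random feature map
  set.seed(66)
  tp <- gbseg:::tape_new(params)
  v <- gbseg:::tp_input(tp, array(rnorm(8 * 8 * 16 * 1), dim = c(8, 8, 16, 1)))
  out <- blk$forward(tp, v, "se")
  gate_node <- tp$recs[[out]]$ins[2]
  gates <- gbseg:::tp_value(tp, gate_node)
  expect_true(all(gates > 0 & gates < 1))
})

test_that("forcing cSE gates to one makes the block an identity on features", {
  set.seed(67)
  blk <- cse_block(8, 4)
  params <- blk$init("se")
  x <- array(rnorm(6 * 6 * 8), dim = c(6, 6, 8, 1))
  tp <- gbseg:::tape_new(params)
  v <- gbseg:::tp_input(tp, x)
  out <- blk$forward(tp, v, "se", force_gates = 1)
  expect_equal(gbseg:::tp_value(tp, out), x, tolerance = 1e-12)
})

test_that("SEU-Net with gates forced to one predicts like a weight-matched U-Net", {
  set.seed(68)
  se <- build_model(tiny_spec("seunet"))
  un <- build_model(tiny_spec("unet"))
  shared <- intersect(names(un$params), names(se$params))
  un$params[shared] <- se$params[shared]
  x <- array(runif(16 * 16), dim = c(16, 16, 1, 1))
  expect_equal(predict(se, x, force_gates = 1), predict(un, x), tolerance = 1e-10)
})

test_that("MCA block keeps the stage's channel count in every configuration", {
  set.seed(69)
  for (ms in c(TRUE, FALSE)) for (att in c(TRUE, FALSE)) {
    spec <- tiny_spec("mcau", enable_multiscale_conv = ms,
                      enable_channel_attention = att)
    blk <- mca_block(4L, 8L, spec)
    tp <- gbseg:::tape_new(blk$init("enc2"))
    v <- gbseg:::tp_input(tp, array(rnorm(8 * 8 * 4), dim = c(8, 8, 4, 1)))
    out <- blk$forward(tp, v, "enc2")
    expect_identical(dim(gbseg:::tp_value(tp, out)), c(8L, 8L, 8L, 1L))
  }
})

test_that("with both parts disabled the MCA stage is the baseline conv pair", {
  spec <- tiny_spec("mcau", enable_multiscale_conv = FALSE,
                    enable_channel_attention = FALSE)
  blk <- mca_block(4L, 8L, spec)
  params <- blk$init("enc2")
  expect_setequal(names(params), c("enc2_conv1", "enc2_conv2"))
  expect_identical(dim(params$enc2_conv1$W), c(3L, 3L, 4L, 8L))
})

test_that("multi-scale descriptors coincide on spatially constant input", {
  # pooling a constant map at any factor leaves its global average unchanged,
  # so the three attention descriptors are equal and combining is a no-op
  x <- array(0, dim = c(8, 8, 3, 2))
  for (c_ in 1:3) x[, , c_, ] <- c_ * 1.5
  tp <- gbseg:::tape_new(list())
  v <- gbseg:::tp_input(tp, x)
  d0 <- gbseg:::tp_value(tp, gbseg:::tp_gap(tp, v))
  p2 <- gbseg:::tp_avgpool(tp, v, 2)
  d2 <- gbseg:::tp_value(tp, gbseg:::tp_gap(tp, p2))
  p4 <- gbseg:::tp_avgpool(tp, v, 4)
  d4 <- gbseg:::tp_value(tp, gbseg:::tp_gap(tp, p4))
  expect_equal(d0, d2, tolerance = 1e-14)
  expect_equal(d0, d4, tolerance = 1e-14)
})

test_that("forcing MCAU-Net gates to one equals disabling the attention part", {
  set.seed(70)
  on <- build_model(tiny_spec("mcau", enable_channel_attention = TRUE))
  off <- build_model(tiny_spec("mcau", enable_channel_attention = FALSE))
  shared <- intersect(names(off$params), names(on$params))
  off$params[shared] <- on$params[shared]
  for (nm in ls(on$state)) off$state[[nm]] <- on$state[[nm]]
  x <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  expect_equal(predict(on, x, force_gates = 1), predict(off, x), tolerance = 1e-5)
})
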