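test_that("the learning-rate schedule follows its closed form", {
  cfg <- training_preset("mcau2")
  expect_equal(lr_at(cfg, 0), 5e-4)
  expect_equal(lr_at(cfg, 800), 5e-4 * 0.96, tolerance = 1e-15)
  expect_equal(lr_at(cfg, 400), 5e-4 * 0.96^0.5, tolerance = 1e-15)
  # no-decay rows keep lr0 at every step
  un <- training_preset("unet")
  expect_equal(lr_at(un, 0), 3e-6)
  expect_equal(lr_at(un, 10000), 3e-6)
  expect_error(lr_at(cfg, -1), "non-negative")
})

test_that("the schedule matches a step-by-step multiplicative-update oracle", {
  cfg <- training_preset("mcau2")
  factor <- cfg$decay_rate^(1 / cfg$decay_steps)
  max_step <- 5000L
  oracle <- cfg$lr0 * cumprod(rep(factor, max_step)) # oracle[s] = lr at step s
  set.seed(71)
  steps <- sample(max_step, 200)
  for (s in steps)
    expect_equal(lr_at(cfg, s), oracle[s], tolerance = 1e-12)
})

test_that("published presets carry the reference hyperparameter rows", {
  rows <- list(
    unet = list(lr0 = 3e-6, steps = NULL, rate = NULL),
    seunet = list(lr0 = 6e-5, steps = 1200L, rate = 0.96),
    mcau1 = list(lr0 = 4e-4, steps = 800L, rate = 0.96),
    mcau2 = list(lr0 = 5e-4, steps = 800L, rate = 0.96),
    mcau3 = list(lr0 = 4e-4, steps = 800L, rate = 0.96))
  for (nm in names(rows)) {
    cfg <- training_preset(nm)
    expect_equal(cfg$batch_size, 4L)
    expect_equal(cfg$epochs, 80L)
    expect_equal(cfg$lr0, rows[[nm]]$lr0)
    expect_equal(cfg$decay_steps, rows[[nm]]$steps)
    expect_equal(cfg$decay_rate, rows[[nm]]$rate)
    expect_equal(cfg$loss, "dice")
  }
  expect_equal(training_preset("mcau3")$model$n_mca_blocks, 3L)
})

test_that("train_config validates decay fields", {
  spec <- tiny_spec("unet")
  expect_error(train_config(spec, decay_steps = 800), "together")
  expect_error(train_config(spec, decay_steps = 800, decay_rate = 1.5), "0, 1")
})

test_that("training runs, learns on separable phantoms, and records history", {
  set.seed(72)
  tr <- phantom_dataset(24, phantom_spec(size = c(32, 32), fg_fraction_target = 0.01, seed = 100))
  va <- phantom_dataset(6, phantom_spec(size = c(32, 32), fg_fraction_target = 0.01, seed = 100),
                        indices = 25:30)
  spec <- architecture_spec("mcau", input_size = c(32, 32), depth = 3L,
                            channel_schedule = c(4L, 8L, 16L), n_mca_blocks = 2L)
  cfg <- train_config(spec, batch_size = 4L, epochs = 4L, lr0 = 1e-3,
                      decay_steps = 800L, decay_rate = 0.96, seed = 5L,
                      name = "tiny-mcau")
  run <- train_model(cfg, tr, va, verbose = FALSE)
  expect_s3_class(run, "gb_run")
  expect_equal(nrow(run$history), 4)
  expect_lt(run$history$train_loss[4], run$history$train_loss[1])
  expect_true(all(diff(run$history$lr) < 0))
  expect_gte(run$best_val_dsc, 0)
  # config echo
  expect_equal(run$config$batch_size, 4L)
  expect_equal(run$config$epochs, 4L)
  # tidiers
  expect_equal(tidy(run), run$history)
  g <- glance(run)
  expect_equal(g$best_epoch, run$best_epoch)
  expect_equal(g$model, "tiny-mcau")
})

test_that("training is deterministic given the seed", {
  tr <- phantom_dataset(8, phantom_spec(size = c(32, 32), fg_fraction_target = 0.01, seed = 101))
  va <- phantom_dataset(2, phantom_spec(size = c(32, 32), fg_fraction_target = 0.01, seed = 101),
                        indices = 9:10)
  spec <- architecture_spec("unet", input_size = c(32, 32), depth = 3L,
                            channel_schedule = c(4L, 8L, 16L))
  cfg <- train_config(spec, epochs = 1L, lr0 = 1e-3, seed = 7L)
  r1 <- train_model(cfg, tr, va, verbose = FALSE)
  r2 <- train_model(cfg, tr, va, verbose = FALSE)
  expect_identical(r1$history$train_loss[1], r2$history$train_loss[1])
  expect_identical(r1$history$val_dsc[1], r2$history$val_dsc[1])
})

test_that("evaluation composes per-case metrics and honours degenerate models", {
  set.seed(73)
  test_set <- phantom_dataset(6, phantom_spec(size = c(32, 32), fg_fraction_target = 0.01, seed = 102))
  spec <- architecture_spec("unet", input_size = c(32, 32), depth = 3L,
                            channel_schedule = c(4L, 8L, 16L))
  m <- build_model(spec)
  ev <- evaluate_model(m, test_set)
  expect_s3_class(ev, "gb_eval")
  expect_equal(nrow(ev$cases), 6)
  expect_equal(ev$aggregate, aggregate_metrics(ev$cases))
  expect_equal(glance(ev)$n_cases, 6)
  # a constant-background model hits the empty-prediction policy on every case
  m$params$out$b <- -25
  ev0 <- evaluate_model(m, test_set)
  expect_equal(ev0$aggregate$mean[ev0$aggregate$metric == "dsc"], 0)
  expect_equal(ev0$aggregate$mean[ev0$aggregate$metric == "rvd"], 1)
  expect_equal(ev0$aggregate$mean[ev0$aggregate$metric == "hd"],
               sqrt(2) * 31, tolerance = 1e-12)
})

test_that("evaluation writes reports and prediction overlays", {
  set.seed(74)
  dir <- withr::local_tempdir()
  test_set <- phantom_dataset(2, phantom_spec(size = c(32, 32), fg_fraction_target = 0.01, seed = 103))
  spec <- architecture_spec("unet", input_size = c(32, 32), depth = 3L,
                            channel_schedule = c(4L, 8L, 16L))
  ev <- evaluate_model(build_model(spec), test_set, out_dir = dir,
                       write_predictions = TRUE)
  expect_true(file.exists(file.path(dir, "metrics_cases.csv")))
  expect_true(file.exists(file.path(dir, "predictions", "pred_0001.png")))
  expect_true(file.exists(file.path(dir, "predictions", "overlay_0001.png")))
})

test_that("model comparison tabulates one row per model x seed plus summaries", {
  set.seed(75)
  all <- phantom_dataset(14, phantom_spec(size = c(32, 32), fg_fraction_target = 0.01, seed = 104))
  data <- list(train = all[1:8], val = all[9:10], test = all[11:14])
  spec <- architecture_spec("unet", input_size = c(32, 32), depth = 3L,
                            channel_schedule = c(4L, 8L, 16L))
  cfg <- train_config(spec, epochs = 1L, lr0 = 1e-3, name = "unet")
  tab <- compare_models(list(unet = cfg), data, replicate_seeds = 1L,
                        verbose = FALSE)
  expect_equal(names(tab),
               c("model", "seed", "dsc", "jsc", "ppv", "se", "hd", "rvd", "voe"))
  expect_equal(nrow(tab), 2) # one run + the mean row
  # the single-seed summary equals the run itself
  expect_equal(unlist(tab[1, -(1:2)]), unlist(tab[2, -(1:2)]), tolerance = 1e-12)
  # and the run row equals an independent train+evaluate with that seed
  cfg1 <- cfg; cfg1$seed <- 1L
  run <- train_model(cfg1, data$train, data$val, verbose = FALSE)
  ev <- evaluate_model(run$model, data$test)
  expect_equal(tab$dsc[1], ev$aggregate$mean[ev$aggregate$metric == "dsc"],
               tolerance = 1e-12)
})

test_that("the ablation grid is runnable from config alone", {
  grid <- list(
    baseline = tiny_spec("mcau", enable_multiscale_conv = FALSE,
                         enable_channel_attention = FALSE),
    multiscale_only = tiny_spec("mcau", enable_multiscale_conv = TRUE,
                                enable_channel_attention = FALSE),
    attention_only = tiny_spec("mcau", enable_multiscale_conv = FALSE,
                               enable_channel_attention = TRUE),
    full = tiny_spec("mcau"))
  set.seed(76)
  x <- array(runif(16 * 16), dim = c(16, 16, 1, 1))
  for (spec in grid) {
    p <- predict(build_model(spec), x)
    expect_identical(dim(p), c(16L, 16L, 1L, 1L))
  }
})
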