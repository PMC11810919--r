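#' Training configuration
#'
#' Bundles every knob of a training run: the architecture, batch size,
#' epochs, the initial learning rate with its continuous exponential decay
#' (\code{lr0 * decay_rate^(step / decay_steps)}; no decay fields means a
#' constant rate), the loss, the validation binarization threshold and the
#' seed. The published hyperparameter table is available through
#' \code{\link{training_preset}}.
#'
#' @param model An \code{\link{architecture_spec}}.
#' @param batch_size Samples per gradient step (default 4).
#' @param epochs Passes over the training set (default 80).
#' @param lr0 Initial learning rate.
#' @param decay_steps,decay_rate Exponential decay parameters; both
#'   \code{NULL} for a constant rate. \code{decay_rate} must be in (0, 1].
#' @param loss \code{"dice"} or \code{"bce"}.
#' @param threshold Binarization threshold for per-epoch validation.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @param eps Dice smoothing constant.
#' @param name Optional label used in comparison tables.
#' @return An object of class \code{gb_train_config}.
#' @export
train_config <- function(model, batch_size = 4L, epochs = 80L, lr0 = 5e-4,
                         decay_steps = NULL, decay_rate = NULL,
                         loss = c("dice", "bce"), threshold = 0.5,
                         seed = 1L, eps = 1e-6, name = NULL) {
  loss <- match.arg(loss)
  stopifnot(inherits(model, "gb_arch_spec"), batch_size >= 1, epochs >= 1)
  if (xor(is.null(decay_steps), is.null(decay_rate)))
    stop("decay_steps and decay_rate must be given together", call. = FALSE)
  if (!is.null(decay_rate) && (decay_rate <= 0 || decay_rate > 1))
    stop("decay_rate must be in (0, 1]", call. = FALSE)
  if (is.null(name)) name <- model$variant
  structure(list(model = model, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0,
                 decay_steps = decay_steps, decay_rate = decay_rate,
                 loss = loss, threshold = threshold, seed = as.integer(seed),
                 eps = eps, name = name),
            class = "gb_train_config")
}

#' Published training presets
#'
#' The per-model hyperparameter rows used at full scale: batch size 4, 80
#' epochs, and per-model learning-rate schedules (U-Net 3e-6 with no decay;
#' SEU-Net 6e-5 decayed by 0.96 every 1200 steps; the three MCAU-Net
#' variants 4e-4/5e-4/4e-4 decayed by 0.96 every 800 steps).
#'
#' @param name One of \code{"unet"}, \code{"seunet"}, \code{"mcau1"},
#'   \code{"mcau2"}, \code{"mcau3"}.
#' @param input_size Spatial size of the input slices.
#' @param seed Seed stored in the config.
#' @return A \code{\link{train_config}}.
#' @export
training_preset <- function(name = c("unet", "seunet", "mcau1", "mcau2", "mcau3"),
                            input_size = c(256L, 256L), seed = 1L) {
  name <- match.arg(name)
  row <- switch(name,
    unet = list(spec = architecture_spec("unet", input_size = input_size),
                lr0 = 3e-6, steps = NULL, rate = NULL),
    seunet = list(spec = architecture_spec("seunet", input_size = input_size),
                  lr0 = 6e-5, steps = 1200L, rate = 0.96),
    mcau1 = list(spec = architecture_spec("mcau", input_size = input_size,
                                          n_mca_blocks = 1L),
                 lr0 = 4e-4, steps = 800L, rate = 0.96),
    mcau2 = list(spec = architecture_spec("mcau", input_size = input_size,
                                          n_mca_blocks = 2L),
                 lr0 = 5e-4, steps = 800L, rate = 0.96),
    mcau3 = list(spec = architecture_spec("mcau", input_size = input_size,
                                          n_mca_blocks = 3L),
                 lr0 = 4e-4, steps = 800L, rate = 0.96))
  train_config(row$spec, batch_size = 4L, epochs = 80L, lr0 = row$lr0,
               decay_steps = row$steps, decay_rate = row$rate,
               loss = "dice", seed = seed, name = name)
}

#' Desk-scale (smoke) configuration
#'
#' A deliberately small configuration for laptop-scale experiments on
#' synthetic phantoms: 64x64 inputs, a base width of 8 channels
#' (schedule 8/16/32/64/128), 10 epochs, batch 4, Dice loss. The learning
#' schedule keeps the published MCAU-Net-2 values (5e-4 decayed by 0.96
#' every 800 steps), which transfer well to this scale; a shared schedule is
#' used for every variant so that desk-scale comparisons reflect the
#' architectures rather than per-model tuning.
#'
#' @param variant \code{"unet"}, \code{"seunet"} or \code{"mcau"}.
#' @param n_mca_blocks MCA blocks for the \code{"mcau"} variant.
#' @param input_size Spatial input size (default 64x64).
#' @param epochs Training epochs (default 10).
#' @param seed Seed.
#' @param ... Passed on to \code{\link{train_config}}.
#' @return A \code{\link{train_config}}.
#' @export
smoke_config <- function(variant = c("mcau", "unet", "seunet"),
                         n_mca_blocks = 2L, input_size = c(64L, 64L),
                         epochs = 10L, seed = 42L, ...) {
  variant <- match.arg(variant)
  spec <- architecture_spec(variant, input_size = input_size,
                            channel_schedule = c(8L, 16L, 32L, 64L, 128L),
                            n_mca_blocks = n_mca_blocks)
  name <- if (variant == "mcau") paste0("mcau", n_mca_blocks) else variant
  train_config(spec, batch_size = 4L, epochs = epochs, lr0 = 5e-4,
               decay_steps = 800L, decay_rate = 0.96, loss = "dice",
               seed = seed, name = name, ...)
}

#' Learning rate at a training step
#'
#' Continuous (non-staircase) exponential decay
#' \code{lr0 * decay_rate^(step / decay_steps)}; configs without decay
#' fields keep \code{lr0} at every step.
#'
#' @param config A \code{\link{train_config}}.
#' @param step Non-negative integer step (gradient update count).
#' @return The learning rate.
#' @export
#' @examples
#' cfg <- training_preset("mcau2")
#' lr_at(cfg, 0)    # 5e-4
#' lr_at(cfg, 800)  # 4.8e-4
lr_at <- function(config, step) {
  if (any(step < 0)) stop("step must be non-negative", call. = FALSE)
  if (is.null(config$decay_steps)) return(rep(config$lr0, length(step)))
  config$lr0 * config$decay_rate^(step / config$decay_steps)
}

## ---- optimiser -----------------------------------------------------------

adam_new <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) lapply(p, function(a) a * 0))
  st$v <- st$m
  st$t <- 0L
  st
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      m <- beta1 * st$m[[nm]][[f]] + (1 - beta1) * g
      v <- beta2 * st$v[[nm]][[f]] + (1 - beta2) * g^2
      st$m[[nm]][[f]] <- m
      st$v[[nm]][[f]] <- v
      # m/v inherit the parameter's shape from initialisation; g may be a
      # bare vector (bias/bn gradients), which broadcasts elementwise.
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  params
}

## ---- training ------------------------------------------------------------

samples_to_arrays <- function(samples) {
  d <- dim(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, dim = c(d, 1L, n))
  g <- array(0, dim = c(d, 1L, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- samples[[i]]$image
    g[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, g = g)
}

clone_state <- function(state) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(state)) out[[nm]] <- state[[nm]]
  out
}

#' Train a segmentation model
#'
#' Seeded end-to-end training: builds the model, iterates mini-batches with
#' Adam under the config's learning-rate schedule, computes the validation
#' mean DSC after every epoch with the metrics module, and keeps the
#' weights of the best-validation-DSC epoch.
#'
#' @param config A \code{\link{train_config}}.
#' @param train_set,val_set Non-empty lists of \code{gb_sample}s whose size
#'   matches \code{config$model$input_size}.
#' @param verbose Print per-epoch progress.
#' @return An object of class \code{gb_run}: the best model
#'   (\code{$model}), the per-epoch history tibble (\code{$history}), the
#'   best epoch and its validation DSC, and the config echo.
#' @export
train_model <- function(config, train_set, val_set, verbose = interactive()) {
  stopifnot(inherits(config, "gb_train_config"),
            length(train_set) > 0, length(val_set) > 0)
  set.seed(config$seed)
  model <- build_model(config$model)
  opt <- adam_new(model$params)
  tr <- samples_to_arrays(train_set)
  va <- samples_to_arrays(val_set)
  n <- length(train_set)
  step <- 0L
  history <- vector("list", config$epochs)
  best <- list(val_dsc = -Inf, epoch = 0L, params = NULL, state = NULL)
  for (epoch in seq_len(config$epochs)) {
    idx <- sample(n)
    losses <- c()
    for (i in seq(1, n, by = config$batch_size)) {
      take <- idx[i:min(i + config$batch_size - 1, n)]
      xb <- tr$x[, , , take, drop = FALSE]
      gb <- tr$g[, , , take, drop = FALSE]
      fw <- gb_forward(model, xb, training = TRUE)
      p <- tp_value(fw$tape, fw$out)
      loss <- if (config$loss == "dice") dice_loss(p, gb, config$eps)
              else bce_loss(p, gb)
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             ", step ", step, call. = FALSE)
      dL <- if (config$loss == "dice") dice_loss_grad(p, gb, config$eps)
            else bce_loss_grad(p, gb)
      grads <- tape_backward(fw$tape, fw$out, dL)
      model$params <- adam_step(model$params, grads, opt,
                                lr = lr_at(config, step))
      step <- step + 1L
      losses <- c(losses, loss)
    }
    val_dsc <- validation_dsc(model, va, config$threshold)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(losses), val_dsc = val_dsc,
      lr = lr_at(config, step - 1L))
    if (val_dsc > best$val_dsc) {
      best <- list(val_dsc = val_dsc, epoch = epoch, params = model$params,
                   state = clone_state(model$state))
    }
    if (isTRUE(verbose))
      message(sprintf("epoch %2d/%d  loss %.4f  val DSC %.4f",
                      epoch, config$epochs, mean(losses), val_dsc))
  }
  best_model <- model
  best_model$params <- best$params
  best_model$state <- best$state
  structure(list(model = best_model, final_model = model,
                 history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, best_val_dsc = best$val_dsc,
                 config = config),
            class = "gb_run")
}

validation_dsc <- function(model, va, threshold) {
  p <- predict(model, va$x)
  cases <- lapply(seq_len(dim(p)[4]), function(i)
    evaluate_case(p[, , 1, i], va$g[, , 1, i], threshold))
  cases <- dplyr::bind_rows(cases)
  kept <- cases$dsc[!cases$truth_empty]
  if (length(kept) == 0) return(NA_real_)
  mean(kept)
}

#' @export
print.gb_run <- function(x, ...) {
  cat(sprintf("<gb_run %s: %d epochs, best val DSC %.4f (epoch %d)>\n",
              x$config$name, nrow(x$history), x$best_val_dsc, x$best_epoch))
  invisible(x)
}

## ---- evaluation ----------------------------------------------------------

#' Evaluate a model on a test set
#'
#' Predicts every test sample, computes the seven per-case metrics and
#' their cohort aggregate. Optionally writes the per-case CSV, aggregate
#' JSON, box-plot CSV, and prediction/overlay PNGs.
#'
#' @param model A \code{gb_model} (e.g. \code{run$model}).
#' @param test_set Non-empty list of \code{gb_sample}s.
#' @param threshold Binarization threshold.
#' @param out_dir Optional output directory.
#' @param write_predictions Write predicted masks and overlays as PNGs
#'   (requires \code{out_dir}).
#' @return An object of class \code{gb_eval} with \code{$cases} (per-case
#'   tibble) and \code{$aggregate} (from \code{\link{aggregate_metrics}}).
#' @export
evaluate_model <- function(model, test_set, threshold = 0.5, out_dir = NULL,
                           write_predictions = FALSE) {
  stopifnot(length(test_set) > 0)
  arr <- samples_to_arrays(test_set)
  p <- predict(model, arr$x)
  cases <- purrr::map_dfr(seq_along(test_set), function(i) {
    r <- evaluate_case(p[, , 1, i], arr$g[, , 1, i], threshold)
    dplyr::bind_cols(tibble::tibble(case = i,
                                    patient_id = test_set[[i]]$patient_id), r)
  })
  agg <- aggregate_metrics(cases)
  if (!is.null(out_dir)) {
    write_metric_reports(cases, agg, out_dir)
    if (isTRUE(write_predictions)) {
      pd <- file.path(out_dir, "predictions")
      dir.create(pd, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_along(test_set)) {
        pm <- binarize(p[, , 1, i], threshold)
        write_slice_png(pm, file.path(pd, sprintf("pred_%04d.png", i)))
        overlay <- overlay_rgb(test_set[[i]]$image, pm, arr$g[, , 1, i])
        png::writePNG(overlay, file.path(pd, sprintf("overlay_%04d.png", i)))
      }
    }
  }
  structure(list(cases = cases, aggregate = agg, threshold = threshold),
            class = "gb_eval")
}

# RGB overlay: prediction in red, ground truth in green (overlap -> yellow).
overlay_rgb <- function(image, pred_mask, truth_mask) {
  rgb <- array(rep(image, 3), dim = c(dim(image), 3))
  rgb[, , 1][pred_mask == 1] <- 1
  rgb[, , 2][truth_mask == 1] <- 1
  rgb
}

#' @export
print.gb_eval <- function(x, ...) {
  cat(sprintf("<gb_eval: %d cases (%d excluded)>\n",
              x$aggregate$n_cases[1], x$aggregate$n_excluded[1]))
  print(x$aggregate[, c("metric", "mean", "sd", "median")])
  invisible(x)
}

## ---- model comparison ----------------------------------------------------

#' Train and compare several models on a fixed split
#'
#' Trains every config on the shared training/validation partitions for
#' every replicate seed, evaluates each run on the shared test partition,
#' and tabulates the seven metric means. One row per model x seed, plus a
#' \code{"mean"} summary row per model; metric columns are ordered
#' \code{dsc, jsc, ppv, se, hd, rvd, voe}.
#'
#' @param configs Named list of \code{\link{train_config}}s.
#' @param data A list with \code{train}, \code{val}, \code{test} sample
#'   lists (e.g. from \code{\link{split_by_patient}}).
#' @param replicate_seeds Integer vector of training seeds.
#' @param threshold Binarization threshold for evaluation.
#' @param out_dir Optional directory for CSV/JSON output.
#' @param verbose Print progress.
#' @return A tibble with columns \code{model}, \code{seed},
#'   \code{dsc, jsc, ppv, se, hd, rvd, voe}.
#' @export
compare_models <- function(configs, data, replicate_seeds = 1L,
                           threshold = 0.5, out_dir = NULL,
                           verbose = interactive()) {
  rows <- list()
  for (cfg in configs) {
    for (sd in replicate_seeds) {
      cfg_s <- cfg
      cfg_s$seed <- as.integer(sd)
      if (isTRUE(verbose)) message("training ", cfg$name, " (seed ", sd, ")")
      run <- train_model(cfg_s, data$train, data$val, verbose = FALSE)
      ev <- evaluate_model(run$model, data$test, threshold)
      means <- stats::setNames(ev$aggregate$mean, ev$aggregate$metric)
      rows <- c(rows, list(tibble::tibble(
        model = cfg$name, seed = as.integer(sd),
        dsc = means[["dsc"]], jsc = means[["jsc"]], ppv = means[["ppv"]],
        se = means[["se"]], hd = means[["hd"]], rvd = means[["rvd"]],
        voe = means[["voe"]])))
    }
  }
  tab <- dplyr::bind_rows(rows)
  summary <- tab |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(dplyr::across(c("dsc", "jsc", "ppv", "se", "hd", "rvd", "voe"),
                                   mean), .groups = "drop") |>
    dplyr::mutate(seed = NA_integer_, .after = "model")
  out <- dplyr::bind_rows(tab, summary)
  out <- out[order(match(out$model, vapply(configs, `[[`, "", "name"))), ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "model_comparison.json"),
                         dataframe = "rows", digits = NA)
  }
  out
}

#' The packaged phantom benchmark
#'
#' A fixed desk-scale benchmark on synthetic phantoms: 120 training, 24
#' validation and 40 test phantoms at 64x64 (patient-grouped generation),
#' 8 training epochs per run with the smoke configuration, replicated over
#' seeds. Used to check the directional ordering of the model family at a
#' scale that runs on one CPU.
#'
#' @param variants Character vector of \code{\link{smoke_config}} variants;
#'   \code{"mcau"} entries may carry a block-count suffix
#'   (\code{"mcau2"} = 2 blocks).
#' @param seeds Replicate training seeds.
#' @param n_train,n_val,n_test Phantom counts.
#' @param epochs Training epochs per run.
#' @param data_seed Seed of the phantom generator.
#' @param verbose Print progress.
#' @return The \code{\link{compare_models}} tibble.
#' @export
run_phantom_benchmark <- function(variants = c("unet", "mcau2"), seeds = 1:3,
                                  n_train = 120L, n_val = 24L, n_test = 40L,
                                  epochs = 8L, data_seed = 42L,
                                  verbose = interactive()) {
  ps <- phantom_spec(size = c(64L, 64L), seed = data_seed)
  ntot <- n_train + n_val + n_test
  all <- phantom_dataset(ntot, ps)
  data <- list(train = all[seq_len(n_train)],
               val = all[n_train + seq_len(n_val)],
               test = all[n_train + n_val + seq_len(n_test)])
  configs <- lapply(variants, function(v) {
    if (grepl("^mcau", v)) {
      nb <- as.integer(sub("^mcau", "", v))
      if (is.na(nb)) nb <- 2L
      smoke_config("mcau", n_mca_blocks = nb, epochs = epochs)
    } else smoke_config(v, epochs = epochs)
  })
  names(configs) <- vapply(configs, `[[`, "", "name")
  compare_models(configs, data, replicate_seeds = seeds, verbose = verbose)
}
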