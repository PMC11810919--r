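#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training run
#'
#' @param x A \code{gb_run}.
#' @param ... Unused.
#' @return The per-epoch history tibble (\code{epoch}, \code{train_loss},
#'   \code{val_dsc}, \code{lr}).
#' @method tidy gb_run
#' @export
tidy.gb_run <- function(x, ...) x$history

#' One-row summary of a training run
#'
#' @param x A \code{gb_run}.
#' @param ... Unused.
#' @return A one-row tibble: model name, epochs, best epoch and validation
#'   DSC, final training loss, parameter counts.
#' @method glance gb_run
#' @export
glance.gb_run <- function(x, ...) {
  pc <- count_parameters(x$model)
  tibble::tibble(
    model = x$config$name,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_dsc = x$best_val_dsc,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    total_params = pc$total,
    trainable_params = pc$trainable
  )
}

#' Tidy an evaluation
#'
#' @param x A \code{gb_eval}.
#' @param ... Unused.
#' @return The per-case metric tibble.
#' @method tidy gb_eval
#' @export
tidy.gb_eval <- function(x, ...) x$cases

#' One-row summary of an evaluation
#'
#' @param x A \code{gb_eval}.
#' @param ... Unused.
#' @return A one-row tibble of per-metric means plus case counts.
#' @method glance gb_eval
#' @export
glance.gb_eval <- function(x, ...) {
  m <- stats::setNames(x$aggregate$mean, x$aggregate$metric)
  tibble::tibble(dsc = m[["dsc"]], jsc = m[["jsc"]], ppv = m[["ppv"]],
                 se = m[["se"]], hd = m[["hd"]], rvd = m[["rvd"]],
                 voe = m[["voe"]], n_cases = x$aggregate$n_cases[1],
                 n_excluded = x$aggregate$n_excluded[1])
}

#' Plot training curves
#'
#' Training loss and validation DSC per epoch.
#'
#' @param object A \code{gb_run}.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gb_run
#' @export
autoplot.gb_run <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_dsc"),
                           names_to = "series")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("Training run: %s", object$config$name)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Box plots of per-case metrics
#'
#' The cohort distribution of each metric (Tukey boxes, 1.5 IQR whiskers),
#' mirroring the standard way segmentation cohorts are summarised.
#'
#' @param object A \code{gb_eval}.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gb_eval
#' @export
autoplot.gb_eval <- function(object, ...) {
  cases <- dplyr::filter(object$cases, !.data$truth_empty)
  long <- tidyr::pivot_longer(cases, c("dsc", "jsc", "ppv", "se", "hd", "rvd", "voe"),
                              names_to = "metric")
  long$metric <- factor(long$metric,
                        levels = c("dsc", "jsc", "ppv", "se", "hd", "rvd", "voe"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::facet_wrap(~metric, scales = "free", nrow = 2) +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-case segmentation metrics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Show a sample with its mask outline
#'
#' @param s A \code{gb_sample}.
#' @param pred Optional probability or binary matrix overlaid in red.
#' @return A ggplot object.
#' @export
plot_sample <- function(s, pred = NULL) {
  d <- dim(s$image)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(s$image),
    mask = as.vector(s$mask)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mask), breaks = 0.5,
                          colour = "green", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(pred)) {
    df$pred <- as.vector(pred)
    p <- p + ggplot2::geom_contour(data = df, ggplot2::aes(z = .data$pred),
                                   breaks = 0.5, colour = "red",
                                   linewidth = 0.3)
  }
  p
}
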