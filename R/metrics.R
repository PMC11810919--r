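#' Segmentation evaluation metrics
#'
#' The seven per-case metrics used to assess gallbladder segmentations:
#' Dice similarity coefficient (DSC), Jaccard similarity coefficient (JSC),
#' positive predictive value (PPV), sensitivity (SE), Hausdorff distance
#' (HD, pixels), relative volume difference (RVD) and volumetric overlap
#' error (VOE = 1 - JSC).
#'
#' @name metrics
NULL

#' Threshold a probability map
#'
#' @param pred Matrix of probabilities.
#' @param threshold Threshold in \code{(0,1)}; a pixel is foreground iff
#'   \code{p >= threshold}.
#' @return Binary (0/1) matrix.
#' @export
binarize <- function(pred, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  (pred >= threshold) + 0
}

#' Pixel confusion counts
#'
#' @param pred_mask,truth_mask Binary matrices of equal shape.
#' @return A one-row tibble with columns \code{tp}, \code{fp}, \code{fn},
#'   \code{tn}.
#' @export
confusion <- function(pred_mask, truth_mask) {
  if (!identical(dim(pred_mask), dim(truth_mask)))
    stop("masks must have identical shapes", call. = FALSE)
  p <- pred_mask != 0
  g <- truth_mask != 0
  tibble::tibble(tp = sum(p & g), fp = sum(p & !g),
                 fn = sum(!p & g), tn = sum(!p & !g))
}

#' Overlap-based metrics from confusion counts
#'
#' \code{dsc = 2tp/(2tp+fp+fn)}, \code{jsc = tp/(tp+fp+fn)},
#' \code{ppv = tp/(tp+fp)} (0 when nothing is predicted),
#' \code{se = tp/(tp+fn)}, \code{rvd = |fp - fn|/(tp+fn)} (absolute by
#' default; \code{signed = TRUE} keeps the sign of the volume difference),
#' \code{voe = 1 - jsc}.
#'
#' @param counts A one-row tibble/list with \code{tp}, \code{fp}, \code{fn}
#'   (as returned by \code{\link{confusion}}).
#' @param signed Report RVD with its sign instead of the absolute value.
#' @return A one-row tibble with columns \code{dsc}, \code{jsc}, \code{ppv},
#'   \code{se}, \code{rvd}, \code{voe}.
#' @export
overlap_metrics <- function(counts, signed = FALSE) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fn == 0)
    stop("empty ground truth: overlap metrics are undefined", call. = FALSE)
  jsc <- tp / (tp + fp + fn)
  rvd <- ((tp + fp) - (tp + fn)) / (tp + fn)
  tibble::tibble(
    dsc = 2 * tp / (2 * tp + fp + fn),
    jsc = jsc,
    ppv = if (tp + fp == 0) 0 else tp / (tp + fp),
    se = tp / (tp + fn),
    rvd = if (signed) rvd else abs(rvd),
    voe = 1 - jsc
  )
}

#' Hausdorff distance between two masks
#'
#' Symmetric Hausdorff distance between the foreground point sets, in pixel
#' units with Euclidean point-to-point distances:
#' \code{max(sup_a inf_b d(a,b), sup_b inf_a d(a,b))}. \code{percentile}
#' selects a percentile variant (e.g. 0.95 for HD95); the default 1 is the
#' plain maximum.
#'
#' @param pred_mask,truth_mask Non-empty binary matrices of equal shape.
#' @param percentile Quantile of the directed nearest-neighbour distances
#'   (1 = classical Hausdorff).
#' @return Distance in pixels.
#' @export
hausdorff <- function(pred_mask, truth_mask, percentile = 1) {
  if (!identical(dim(pred_mask), dim(truth_mask)))
    stop("masks must have identical shapes", call. = FALSE)
  if (sum(pred_mask != 0) == 0 || sum(truth_mask != 0) == 0)
    stop("both masks must be non-empty", call. = FALSE)
  d <- directed_nn_dists_cpp(matrix(as.integer(pred_mask != 0), nrow(pred_mask)),
                             matrix(as.integer(truth_mask != 0), nrow(truth_mask)))
  if (percentile >= 1) {
    max(max(d$ab), max(d$ba))
  } else {
    max(stats::quantile(d$ab, percentile, names = FALSE),
        stats::quantile(d$ba, percentile, names = FALSE))
  }
}

#' Evaluate one predicted case
#'
#' Binarizes the prediction and computes all seven metrics against the
#' ground truth. Degenerate cases follow a documented policy: an empty
#' prediction against a non-empty truth scores
#' \code{dsc = jsc = ppv = se = 0}, \code{rvd = 1}, \code{voe = 1} and
#' \code{hd} equal to the image diagonal; an empty ground truth yields a row
#' of \code{NA}s flagged \code{truth_empty = TRUE} (such cases are excluded
#' from aggregation but counted).
#'
#' @param pred Probability matrix.
#' @param truth Binary matrix of the same shape.
#' @param threshold Binarization threshold.
#' @param hd_percentile Passed to \code{\link{hausdorff}}.
#' @return A one-row tibble with \code{dsc}, \code{jsc}, \code{ppv},
#'   \code{se}, \code{hd}, \code{rvd}, \code{voe}, \code{truth_empty}.
#' @export
evaluate_case <- function(pred, truth, threshold = 0.5, hd_percentile = 1) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shapes", call. = FALSE)
  pm <- binarize(pred, threshold)
  if (sum(truth != 0) == 0) {
    return(tibble::tibble(dsc = NA_real_, jsc = NA_real_, ppv = NA_real_,
                          se = NA_real_, hd = NA_real_, rvd = NA_real_,
                          voe = NA_real_, truth_empty = TRUE))
  }
  if (sum(pm) == 0) {
    diag_len <- sqrt(sum((dim(truth) - 1)^2))
    return(tibble::tibble(dsc = 0, jsc = 0, ppv = 0, se = 0, hd = diag_len,
                          rvd = 1, voe = 1, truth_empty = FALSE))
  }
  om <- overlap_metrics(confusion(pm, truth))
  hd <- hausdorff(pm, truth, hd_percentile)
  tibble::tibble(dsc = om$dsc, jsc = om$jsc, ppv = om$ppv, se = om$se,
                 hd = hd, rvd = om$rvd, voe = om$voe, truth_empty = FALSE)
}

#' Aggregate per-case metric reports
#'
#' Cohort statistics per metric: mean, sample standard deviation (n-1
#' denominator; 0 with \code{sd_defined = FALSE} for a single case), median,
#' quartiles (linear interpolation), and Tukey whiskers (most extreme
#' observations within 1.5 IQR of the quartiles). Cases flagged
#' \code{truth_empty} are excluded and counted in \code{n_excluded}.
#'
#' @param reports A tibble of per-case rows as returned by
#'   \code{\link{evaluate_case}} (bound together).
#' @return A tibble with one row per metric and columns \code{metric},
#'   \code{mean}, \code{sd}, \code{median}, \code{q1}, \code{q3},
#'   \code{whisker_low}, \code{whisker_high}, \code{n_cases},
#'   \code{n_excluded}, \code{sd_defined}.
#' @export
aggregate_metrics <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- dplyr::bind_rows(reports)
  if (nrow(reports) == 0) stop("no reports to aggregate", call. = FALSE)
  if (!"truth_empty" %in% names(reports)) reports$truth_empty <- FALSE
  kept <- dplyr::filter(reports, !.data$truth_empty)
  n_excluded <- nrow(reports) - nrow(kept)
  if (nrow(kept) == 0) stop("all cases had empty ground truth", call. = FALSE)
  metric_names <- c("dsc", "jsc", "ppv", "se", "hd", "rvd", "voe")
  purrr::map_dfr(metric_names, function(m) {
    x <- kept[[m]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    tibble::tibble(
      metric = m,
      mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else 0,
      median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
      whisker_high = max(x[x <= q[3] + 1.5 * iqr]),
      n_cases = length(x), n_excluded = n_excluded,
      sd_defined = length(x) > 1
    )
  })
}

#' Write per-case and aggregate reports
#'
#' Per-case metrics go to CSV (one row per case), the aggregate to JSON, and
#' the box-plot statistics (median/quartiles/whiskers) to a separate CSV for
#' external plotting.
#'
#' @param cases Per-case tibble.
#' @param aggregate Aggregate tibble from \code{\link{aggregate_metrics}}.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_metric_reports <- function(cases, aggregate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cases, file.path(dir, "metrics_cases.csv"), row.names = FALSE)
  jsonlite::write_json(aggregate, file.path(dir, "metrics_aggregate.json"),
                       dataframe = "rows", digits = NA)
  utils::write.csv(
    aggregate[, c("metric", "median", "q1", "q3", "whisker_low", "whisker_high")],
    file.path(dir, "metrics_boxstats.csv"), row.names = FALSE)
  invisible(dir)
}
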