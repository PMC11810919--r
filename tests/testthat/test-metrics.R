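test_that("binarize uses an inclusive threshold", {
  expect_equal(binarize(matrix(0.5), 0.5)[1, 1], 1)
  expect_equal(binarize(matrix(c(0.4, 0.6), 1), 0.5), matrix(c(0, 1), 1))
  expect_equal(sum(binarize(matrix(0.2, 3, 3), 0.5)), 0)
})

test_that("confusion counts match the exhaustive per-pixel tally", {
  m <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(confusion(m, m)[, c("tp", "fp", "fn")],
               tibble::tibble(tp = 2L, fp = 0L, fn = 0L))
  a <- matrix(c(1, 0, 0, 0), 2, 2); b <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(confusion(a, b), tibble::tibble(tp = 0L, fp = 1L, fn = 2L, tn = 1L))
  set.seed(41)
  for (i in 1:10) {
    p <- random_mask(4, 4, 0.4, nonempty = FALSE)
    g <- random_mask(4, 4, 0.4, nonempty = FALSE)
    o <- oracle_metrics(p, g)
    cc <- confusion(p, g)
    expect_equal(cc$tp, o$tp)
    expect_equal(cc$fp, o$fp)
    expect_equal(cc$fn, o$fn)
    expect_equal(cc$tn, o$tn)
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 16L)
  }
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("overlap metrics reproduce hand-computed cases", {
  r <- overlap_metrics(list(tp = 1, fp = 1, fn = 1))
  expect_equal(unlist(r),
               c(dsc = 0.5, jsc = 1 / 3, ppv = 0.5, se = 0.5, rvd = 0, voe = 2 / 3))
  r2 <- overlap_metrics(list(tp = 5, fp = 0, fn = 0))
  expect_equal(unlist(r2), c(dsc = 1, jsc = 1, ppv = 1, se = 1, rvd = 0, voe = 0))
  # prediction twice the truth's area, fully covering it
  r3 <- overlap_metrics(list(tp = 7, fp = 7, fn = 0))
  expect_equal(r3$rvd, 1)
  expect_equal(r3$se, 1)
  expect_equal(r3$ppv, 0.5)
  expect_error(overlap_metrics(list(tp = 0, fp = 3, fn = 0)), "empty ground truth")
  # signed variant keeps under-segmentation negative
  expect_equal(overlap_metrics(list(tp = 2, fp = 0, fn = 2), signed = TRUE)$rvd, -0.5)
})

test_that("DSC/JSC algebraic identities hold on random counts", {
  set.seed(42)
  for (i in 1:50) {
    cts <- list(tp = sample(1:50, 1), fp = sample(0:50, 1), fn = sample(0:50, 1))
    r <- overlap_metrics(cts)
    expect_equal(r$voe + r$jsc, 1, tolerance = 1e-15)
    expect_equal(r$dsc, 2 * r$jsc / (1 + r$jsc), tolerance = 1e-12)
    expect_lte(r$jsc, r$dsc)
  }
})

test_that("Hausdorff distance matches geometry and the all-pairs oracle", {
  m <- random_mask(6, 6, 0.3)
  expect_equal(hausdorff(m, m), 0)
  a <- matrix(0, 6, 6); a[1, 1] <- 1
  b <- matrix(0, 6, 6); b[4, 5] <- 1
  expect_equal(hausdorff(a, b), 5)
  set.seed(43)
  for (i in 1:25) {
    p <- random_mask(12, 12, 0.15)
    g <- random_mask(12, 12, 0.15)
    expect_equal(hausdorff(p, g), oracle_hausdorff(p, g), tolerance = 1e-12)
    expect_equal(hausdorff(p, g), hausdorff(g, p))
  }
  expect_error(hausdorff(matrix(0, 3, 3), m[1:3, 1:3]), "non-empty")
})

test_that("Hausdorff satisfies the triangle inequality on random triples", {
  set.seed(44)
  for (i in 1:15) {
    a <- random_mask(10, 10, 0.2)
    b <- random_mask(10, 10, 0.2)
    c <- random_mask(10, 10, 0.2)
    expect_lte(hausdorff(a, c), hausdorff(a, b) + hausdorff(b, c) + 1e-12)
  }
})

test_that("hd95 is never larger than the plain Hausdorff distance", {
  set.seed(45)
  for (i in 1:10) {
    p <- random_mask(16, 16, 0.2)
    g <- random_mask(16, 16, 0.2)
    expect_lte(hausdorff(p, g, percentile = 0.95), hausdorff(p, g))
  }
})

test_that("evaluate_case composes the full metric suite", {
  g <- matrix(0, 8, 8); g[3:5, 3:6] <- 1
  perfect <- evaluate_case(g, g)
  expect_equal(unlist(perfect[, c("dsc", "jsc", "ppv", "se", "hd", "rvd", "voe")]),
               c(dsc = 1, jsc = 1, ppv = 1, se = 1, hd = 0, rvd = 0, voe = 0))
  # empty prediction policy
  empty <- evaluate_case(matrix(0, 8, 8), g)
  expect_equal(empty$dsc, 0)
  expect_equal(empty$rvd, 1)
  expect_equal(empty$voe, 1)
  expect_equal(empty$hd, sqrt(2) * 7)
  expect_false(empty$truth_empty)
  # empty truth policy: flagged, not scored
  et <- evaluate_case(g, matrix(0, 8, 8))
  expect_true(et$truth_empty)
  expect_true(is.na(et$dsc))
})

test_that("evaluate_case equals brute-force recomputation on a worked 8x8 pair", {
  set.seed(46)
  prob <- matrix(runif(64), 8, 8)
  g <- random_mask(8, 8, 0.3)
  r <- evaluate_case(prob, g, threshold = 0.5)
  p <- (prob >= 0.5) + 0
  o <- oracle_metrics(p, g)
  expect_equal(r$dsc, o$dsc)
  expect_equal(r$jsc, o$jsc)
  expect_equal(r$ppv, o$ppv)
  expect_equal(r$se, o$se)
  expect_equal(r$rvd, o$rvd)
  expect_equal(r$voe, o$voe)
  expect_equal(r$hd, oracle_hausdorff(p, g), tolerance = 1e-12)
})

test_that("aggregation computes cohort statistics and the 1.5 IQR whiskers", {
  one <- evaluate_case(matrix(c(1, 0), 1), matrix(c(1, 0), 1))
  agg1 <- aggregate_metrics(one)
  expect_equal(agg1$sd, rep(0, 7))
  expect_false(any(agg1$sd_defined))
  two <- tibble::tibble(dsc = c(0.8, 0.9), jsc = c(0.7, 0.8), ppv = c(1, 1),
                        se = c(0.8, 0.9), hd = c(2, 3), rvd = c(0.1, 0),
                        voe = c(0.3, 0.2), truth_empty = FALSE)
  agg2 <- aggregate_metrics(two)
  expect_equal(agg2$mean[agg2$metric == "dsc"], 0.85)
  expect_equal(agg2$sd[agg2$metric == "dsc"], sd(c(0.8, 0.9)), tolerance = 1e-12)
  # outlier excluded from the upper whisker
  vals <- c(1, 2, 3, 4, 100)
  rep5 <- tibble::tibble(dsc = vals, jsc = vals, ppv = vals, se = vals,
                         hd = vals, rvd = vals, voe = vals, truth_empty = FALSE)
  agg5 <- aggregate_metrics(rep5)
  expect_equal(agg5$whisker_high[1], 4)
  expect_equal(agg5$whisker_low[1], 1)
  expect_true(all(agg5$q1 <= agg5$median & agg5$median <= agg5$q3))
})

test_that("truth-empty cases are excluded and counted", {
  g <- matrix(0, 8, 8); g[3:5, 3:6] <- 1
  reports <- dplyr::bind_rows(
    evaluate_case(g, g),
    evaluate_case(g, matrix(0, 8, 8)),
    evaluate_case(matrix(0, 8, 8), g))
  agg <- aggregate_metrics(reports)
  expect_equal(agg$n_cases[1], 2)
  expect_equal(agg$n_excluded[1], 1)
  expect_error(aggregate_metrics(reports[2, ]), "empty ground truth")
})

test_that("metric reports are written as CSV and JSON", {
  dir <- withr::local_tempdir()
  g <- matrix(0, 8, 8); g[3:5, 3:6] <- 1
  cases <- dplyr::bind_rows(evaluate_case(g, g), evaluate_case(matrix(0, 8, 8), g))
  write_metric_reports(cases, aggregate_metrics(cases), dir)
  expect_true(all(file.exists(file.path(dir,
    c("metrics_cases.csv", "metrics_aggregate.json", "metrics_boxstats.csv")))))
  back <- utils::read.csv(file.path(dir, "metrics_cases.csv"))
  expect_equal(nrow(back), 2)
})
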