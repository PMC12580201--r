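# Brute-force one-vs-rest recount used as the independent oracle.
oracle_metrics <- function(truth, pred, K) {
  out <- list()
  N <- length(truth)
  for (k in 0:(K - 1)) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    tn <- sum(truth != k & pred != k)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    out[[k + 1]] <- c(prec, sens, spec, f1)
  }
  list(per_class = do.call(rbind, out), accuracy = mean(truth == pred))
}

test_that("confusion counting matches brute force on random labelings", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      truth <- sample(0:2, 30, replace = TRUE)
      pred <- sample(0:2, 30, replace = TRUE)
      cm <- confusion_matrix(truth, pred)
      ref <- matrix(0L, 3, 3)
      for (i in seq_along(truth)) {
        ref[truth[i] + 1, pred[i] + 1] <- ref[truth[i] + 1, pred[i] + 1] + 1L
      }
      expect_equal(unclass(cm), ref, ignore_attr = TRUE)
      mt <- per_class_metrics(cm)
      orc <- oracle_metrics(truth, pred, 3)
      expect_equal(as.matrix(mt$raw[1:3, 2:5]), orc$per_class,
                   ignore_attr = TRUE, tolerance = 1e-12)
      expect_equal(mt$accuracy_raw, orc$accuracy, tolerance = 1e-12)
    }
  })
  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(c(0, 3), c(0, 1)), "outside 0..2")
})

test_that("perfect prediction gives a diagonal matrix and all-100 metrics", {
  truth <- rep(0:2, each = 4)
  cm <- confusion_matrix(truth, truth)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  mt <- per_class_metrics(cm)
  expect_true(all(as.matrix(mt$table[, 2:5]) == 100))
  expect_equal(mt$accuracy, 100)
})

test_that("the reconstructed reference test matrix reproduces every printed cell", {
  counts <- ref_extdata("reference_confusion_ucm_synthetic.csv")
  cm <- as_confusion_matrix(counts[, -1], class_labels = counts$true_class)
  mt <- per_class_metrics(cm)
  expect_equal(mt$accuracy, 88.57)
  ben <- mt$table[mt$table$class == "Benign", ]
  expect_equal(ben$precision, 88.06)
  expect_equal(ben$sensitivity, 84.29)
  expect_equal(ben$specificity, 94.29)
  expect_equal(ben$f1, 86.13)
  ov <- mt$table[mt$table$class == "Overall", ]
  expect_equal(ov$precision, 88.57)
  expect_equal(ov$sensitivity, 88.57)
  expect_equal(ov$specificity, 94.29)
})

test_that("macro aggregation of the published per-class rows matches the overall rows", {
  ucm <- ref_extdata("reference_class_metrics_ucm.csv")
  expect_equal(round_half_up(mean(ucm$precision), 2), 88.57)
  expect_equal(round_half_up(mean(ucm$specificity), 2), 94.29)
  ocm <- ref_extdata("reference_class_metrics_ocm.csv")
  expect_equal(round_half_up(mean(ocm$f1), 2), 87.64)
  expect_equal(round_half_up(mean(ocm$sensitivity), 2), 87.75)
})

test_that("micro accuracy equals macro sensitivity for balanced classes", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      truth <- rep(0:2, each = 25)
      pred <- sample(0:2, 75, replace = TRUE)
      mt <- per_class_metrics(confusion_matrix(truth, pred))
      macro_sens <- mt$raw$sensitivity[mt$raw$class == "Overall"]
      expect_equal(mt$accuracy_raw, macro_sens, tolerance = 1e-12)
    }
  })
})

test_that("zero predicted positives warn and define precision as 0", {
  cm <- confusion_matrix(c(0, 0, 1, 1, 2, 2), c(0, 0, 0, 0, 0, 0))
  expect_warning(mt <- per_class_metrics(cm), "zero predicted positives")
  expect_equal(mt$raw$precision[2:3], c(0, 0))
})

test_that("Wald intervals reproduce the published values exactly", {
  ci <- accuracy_ci(166, 210)
  expect_equal(ci$accuracy, 79.05)
  expect_equal(ci$lower, 73.54)
  expect_equal(ci$upper, 84.55)
  perfect <- accuracy_ci(210, 210)
  expect_equal(c(perfect$lower, perfect$upper), c(100, 100))
  half <- accuracy_ci(105, 210)
  expect_equal(half$mean, 0.5)
  expect_equal(round_half_up((half$upper - half$lower) / 2, 2), 6.76)
  expect_error(accuracy_ci(5, 0), ">= 1")
  expect_error(accuracy_ci(11, 10), "correct <= n")
})

test_that("CI width shrinks monotonically with n at fixed proportion", {
  widths <- vapply(c(50, 100, 200, 400, 800), function(n) {
    ci <- accuracy_ci(round(0.8 * n), n)
    ci$upper - ci$lower
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("metric and confusion tables export to CSV with labels", {
  cm <- confusion_matrix(rep(0:2, each = 5), rep(c(0, 1, 2), 5))
  mt <- per_class_metrics(cm)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(mt, p1)
  write_confusion_csv(cm, p2)
  expect_equal(read.csv(p1)$class, c(class_levels(), "Overall"))
  expect_equal(read.csv(p2, check.names = FALSE)$true_class, class_levels())
})
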