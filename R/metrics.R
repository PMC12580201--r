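#' Multi-class confusion matrix
#'
#' Counts with rows indexing the true class and columns the predicted
#' class.  Labels may be 0-based integer codes or class-name strings
#' matched against `class_labels`.
#'
#' @param truth true labels.
#' @param predicted predicted labels (same length).
#' @param class_labels ordered class names (default the package's standard
#'   three-class order).
#' @return a `confusion_matrix`: K x K integer matrix with named
#'   dimensions.
#' @export
confusion_matrix <- function(truth, predicted, class_labels = class_levels()) {
  if (length(truth) == 0) stop("empty label vectors", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  K <- length(class_labels)
  to_code <- function(x, what) {
    if (is.numeric(x)) {
      x <- as.integer(x)
      if (any(x < 0 | x >= K)) {
        stop(what, " labels outside 0..", K - 1, call. = FALSE)
      }
      x
    } else {
      m <- match(as.character(x), class_labels)
      if (anyNA(m)) {
        stop(what, " labels not in {", paste(class_labels, collapse = ", "),
             "}", call. = FALSE)
      }
      m - 1L
    }
  }
  t_ <- to_code(truth, "truth")
  p_ <- to_code(predicted, "predicted")
  cm <- matrix(0L, K, K, dimnames = list(true = class_labels,
                                         predicted = class_labels))
  for (i in seq_along(t_)) {
    cm[t_[i] + 1L, p_[i] + 1L] <- cm[t_[i] + 1L, p_[i] + 1L] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Coerce a plain count matrix to a confusion matrix
#' @param counts K x K non-negative integer matrix (rows = true class).
#' @param class_labels ordered class names.
#' @return a `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, class_labels = class_levels()) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0),
            nrow(counts) == length(class_labels))
  m <- matrix(as.integer(counts), nrow(counts),
              dimnames = list(true = class_labels, predicted = class_labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Per-class one-vs-rest metrics with macro aggregation
#'
#' For each class k the one-vs-rest reduction gives TP = `cm[k,k]`,
#' FP = column k total - TP, FN = row k total - TP, TN = N - TP - FP - FN,
#' from which precision TP/(TP+FP), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP) and F1 (harmonic mean of precision and sensitivity) are
#' computed.  The "Overall" row is the unweighted macro mean of the K
#' per-class values; accuracy is trace/N.  Reported values are percentages
#' rounded half-up to 2 decimals; `$raw` keeps full precision.  A class
#' that is never predicted has precision defined as 0 (with a warning).
#'
#' @param cm a [confusion_matrix()].
#' @return a `metrics_table`: list with `table` (per-class + Overall rows,
#'   rounded %), `raw` (unrounded fractions), `accuracy` (rounded %),
#'   `accuracy_raw` (fraction), `n`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- unclass(cm)
  N <- sum(counts)
  if (N == 0) stop("confusion matrix is empty", call. = FALSE)
  K <- nrow(counts)
  labels <- rownames(counts)
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  tn <- N - tp - fp - fn
  if (any(tp + fp == 0)) {
    warning("class(es) with zero predicted positives: precision set to 0: ",
            paste(labels[tp + fp == 0], collapse = ", "))
  }
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  sensitivity <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  specificity <- ifelse(tn + fp == 0, 0, tn / (tn + fp))
  f1 <- ifelse(precision + sensitivity == 0, 0,
               2 * precision * sensitivity / (precision + sensitivity))
  raw <- data.frame(class = labels, precision = precision,
                    sensitivity = sensitivity, specificity = specificity,
                    f1 = f1, row.names = NULL)
  overall <- data.frame(class = "Overall",
                        precision = mean(precision),
                        sensitivity = mean(sensitivity),
                        specificity = mean(specificity),
                        f1 = mean(f1))
  raw <- rbind(raw, overall)
  table <- raw
  for (col in c("precision", "sensitivity", "specificity", "f1")) {
    table[[col]] <- round_half_up(100 * raw[[col]], 2)
  }
  acc <- sum(tp) / N
  structure(list(table = table, raw = raw,
                 accuracy = round_half_up(100 * acc, 2),
                 accuracy_raw = acc, n = N),
            class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  cat(sprintf("<metrics_table> n = %d, accuracy = %.2f%%\n", x$n, x$accuracy))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Wald (normal-approximation) confidence interval for accuracy
#'
#' For `correct` successes out of `n`, the interval is
#' `100 * (mu +- z * sqrt(mu (1 - mu) / n))` with `mu = correct / n`;
#' bounds are reported in percent, rounded half-up to 2 decimals.
#'
#' @param correct number of correct predictions.
#' @param n number of evaluated cases (>= 1).
#' @param z critical value (default 1.96 for 95%).
#' @return an `accuracy_ci` list: `mean` (fraction), `accuracy` (%), `n`,
#'   `z`, `sigma`, `lower`, `upper` (%).
#' @export
#' @examples
#' accuracy_ci(166, 210) # (73.54, 84.55)
accuracy_ci <- function(correct, n, z = 1.96) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (correct < 0 || correct > n) {
    stop("need 0 <= correct <= n", call. = FALSE)
  }
  mu <- correct / n
  sigma <- sqrt(mu * (1 - mu) / n)
  structure(list(mean = mu, accuracy = round_half_up(100 * mu, 2),
                 n = as.integer(n), z = z, sigma = sigma,
                 lower = round_half_up(100 * (mu - z * sigma), 2),
                 upper = round_half_up(100 * (mu + z * sigma), 2)),
            class = "accuracy_ci")
}

#' @export
print.accuracy_ci <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% (n = %d), %.0f%%-CI (%.2f, %.2f)\n",
              x$accuracy, x$n, 100 * (2 * stats::pnorm(x$z) - 1),
              x$lower, x$upper))
  invisible(x)
}

#' Write a metrics table to CSV
#' @param mt a `metrics_table`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_metrics_csv <- function(mt, path) {
  stopifnot(inherits(mt, "metrics_table"))
  utils::write.csv(mt$table, path, row.names = FALSE)
  invisible(path)
}

#' Write a confusion matrix to CSV with labelled rows/columns
#' @param cm a `confusion_matrix`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  df <- data.frame(true_class = rownames(cm), unclass(cm),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
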