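#' Per-image class-probability matrix
#'
#' The interchange object between model training and ensembling: one row
#' per image, one column per class, rows summing to 1 (tolerance 1e-6).
#'
#' @param probs N x K numeric matrix.
#' @param image_ids length-N unique identifiers.
#' @param class_labels length-K class names, in a fixed order shared by all
#'   ensemble members.
#' @return a `probability_matrix` object.
#' @export
probability_matrix <- function(probs, image_ids, class_labels) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1) stop("need at least one image row", call. = FALSE)
  if (length(image_ids) != nrow(probs)) {
    stop("image_ids length must match rows", call. = FALSE)
  }
  if (anyDuplicated(image_ids)) stop("image_ids must be unique", call. = FALSE)
  if (length(class_labels) != ncol(probs)) {
    stop("class_labels length must match columns", call. = FALSE)
  }
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9)) {
    stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  bad <- abs(rowSums(probs) - 1) > 1e-6
  if (any(bad)) {
    stop(sprintf("%d row(s) do not sum to 1 within 1e-6 (first: %s)",
                 sum(bad), image_ids[which(bad)[1]]), call. = FALSE)
  }
  dimnames(probs) <- list(as.character(image_ids), as.character(class_labels))
  structure(list(probs = probs), class = "probability_matrix")
}

#' @export
print.probability_matrix <- function(x, ...) {
  cat(sprintf("<probability_matrix> %d images x %d classes (%s)\n",
              nrow(x$probs), ncol(x$probs),
              paste(colnames(x$probs), collapse = ", ")))
  print(utils::head(round(x$probs, 4)))
  if (nrow(x$probs) > 6) cat("...\n")
  invisible(x)
}

#' Soft-voting ensemble
#'
#' Averages the members' class probabilities with equal weights and
#' predicts the argmax class per image.  Members must carry identical class
#' labels in identical order; image rows are re-aligned by id if permuted.
#' Exact argmax ties are broken toward the lowest class index and flagged.
#'
#' @param members list of [probability_matrix()] objects (>= 1).
#' @return list with `ensemble` (the averaged `probability_matrix`),
#'   `predicted` (character vector of class labels), `predicted_index`
#'   (0-based integer labels) and `tie` (logical).
#' @export
#' @examples
#' m <- probability_matrix(matrix(c(0.2, 0.5, 0.3), 1), "a",
#'                         c("Normal", "Benign", "Malignant"))
#' soft_vote(list(m))$predicted
soft_vote <- function(members) {
  if (!is.list(members) || length(members) < 1) {
    stop("need at least one ensemble member", call. = FALSE)
  }
  lapply(members, function(m) {
    if (!inherits(m, "probability_matrix")) {
      stop("all members must be probability_matrix objects", call. = FALSE)
    }
  })
  ref_ids <- rownames(members[[1]]$probs)
  ref_classes <- colnames(members[[1]]$probs)
  mats <- lapply(seq_along(members), function(i) {
    p <- members[[i]]$probs
    if (!identical(colnames(p), ref_classes)) {
      stop(sprintf("member %d class labels (%s) differ from member 1 (%s)",
                   i, paste(colnames(p), collapse = ","),
                   paste(ref_classes, collapse = ",")), call. = FALSE)
    }
    ids <- rownames(p)
    if (!identical(ids, ref_ids)) {
      extra <- setdiff(ids, ref_ids)
      missing <- setdiff(ref_ids, ids)
      if (length(extra) || length(missing)) {
        stop(sprintf(
          "member %d image set differs from member 1 (missing: %s; extra: %s)",
          i, paste(utils::head(missing, 5), collapse = ",") %||% "",
          paste(utils::head(extra, 5), collapse = ",")), call. = FALSE)
      }
      p <- p[ref_ids, , drop = FALSE] # same set, permuted order
    }
    p
  })
  avg <- Reduce(`+`, mats) / length(mats)
  pred_idx <- max.col(avg, ties.method = "first") # lowest index wins ties
  is_tie <- vapply(seq_len(nrow(avg)), function(i) {
    sum(avg[i, ] == max(avg[i, ])) > 1L
  }, logical(1))
  if (any(is_tie)) {
    message(sum(is_tie), " tie(s) broken toward the lowest class index")
  }
  list(ensemble = probability_matrix(avg, ref_ids, ref_classes),
       predicted = ref_classes[pred_idx],
       predicted_index = pred_idx - 1L,
       tie = is_tie)
}

#' Write a probability matrix to CSV
#'
#' Header: `image_id`, then one column per class label.  If `vote` is the
#' result of [soft_vote()], `predicted_label` and `tie` columns are added.
#'
#' @param pm a `probability_matrix`, or a [soft_vote()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_probability_csv <- function(pm, path) {
  if (is.list(pm) && !inherits(pm, "probability_matrix") &&
      !is.null(pm$ensemble)) {
    df <- data.frame(image_id = rownames(pm$ensemble$probs),
                     as.data.frame(pm$ensemble$probs, row.names = NULL),
                     predicted_label = pm$predicted, tie = pm$tie,
                     check.names = FALSE)
  } else {
    stopifnot(inherits(pm, "probability_matrix"))
    df <- data.frame(image_id = rownames(pm$probs),
                     as.data.frame(pm$probs, row.names = NULL),
                     check.names = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a probability matrix written by [write_probability_csv()]
#' @param path CSV path.
#' @return a `probability_matrix` (prediction columns, if present, are
#'   dropped).
#' @export
read_probability_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  prob_cols <- setdiff(names(df), c("image_id", "predicted_label", "tie"))
  probability_matrix(as.matrix(df[prob_cols]), df$image_id, prob_cols)
}
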