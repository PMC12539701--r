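#' Evaluation: confusion metrics, municipality rollup, temporal tables,
#' test-retest reliability
#'
#' Producer classification is scored with the multiclass confusion matrix
#' and derived metrics. Because each producer belongs to exactly one
#' municipality, producer predictions also induce municipality predictions
#' (a coarsening, so municipality accuracy can never be lower). Temporal
#' robustness is summarized per sampling visit, and repeatability between
#' the two acquisition rounds is quantified by the Pearson correlation
#' between the per-producer F1 vectors of round 1 and round 2.
#'
#' @name evaluate
NULL

#' Multiclass confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes ordered class list; defaults to the sorted union of both
#'   vectors. Labels outside `classes` are an error.
#' @return a `confusion_matrix`: list with `counts` (n x n integer matrix,
#'   rows = truth, columns = prediction) and `classes`.
#' @export
confusion <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown)) {
    stop("label(s) not in classes: ", paste(unknown, collapse = ", "))
  }
  ft <- factor(y_true, levels = classes)
  fp <- factor(y_pred, levels = classes)
  counts <- unclass(table(ft, fp))
  dimnames(counts) <- list(true = classes, predicted = classes)
  structure(list(counts = counts, classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Metrics derived from a confusion matrix
#'
#' Accuracy is trace over total. Per class: precision is the diagonal over
#' the column sum (0 when the class is never predicted), recall the diagonal
#' over the row sum (0 when the class has no true samples), F1 their
#' harmonic mean (0 when both are 0). Balanced accuracy is the mean recall
#' over classes with support; macro metrics are unweighted means over all
#' classes; weighted metrics weight per-class values by true class counts.
#'
#' @param cm a `confusion_matrix`.
#' @return a `metrics_report` list: `accuracy`, `balanced_accuracy`,
#'   `per_class` (data frame with precision/recall/f1/support),
#'   `macro_precision`, `macro_recall`, `macro_f1`, `weighted_precision`,
#'   `weighted_recall`, `weighted_f1`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$counts
  total <- sum(m)
  if (total == 0) stop("confusion matrix is empty")
  diagv <- diag(m)
  rowsum_ <- rowSums(m)
  colsum_ <- colSums(m)
  precision <- ifelse(colsum_ == 0, 0, diagv / colsum_)
  recall <- ifelse(rowsum_ == 0, 0, diagv / rowsum_)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  support <- rowsum_
  w <- support / total
  structure(
    list(
      accuracy = sum(diagv) / total,
      balanced_accuracy = mean(recall[support > 0]),
      per_class = data.frame(class = cm$classes, precision = precision,
                             recall = recall, f1 = f1, support = support,
                             row.names = NULL),
      macro_precision = mean(precision),
      macro_recall = mean(recall),
      macro_f1 = mean(f1),
      weighted_precision = sum(w * precision),
      weighted_recall = sum(w * recall),
      weighted_f1 = sum(w * f1)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | balanced %.4f | macro P/R/F1 %.4f/%.4f/%.4f | weighted F1 %.4f\n",
              x$accuracy, x$balanced_accuracy, x$macro_precision,
              x$macro_recall, x$macro_f1, x$weighted_f1))
  invisible(x)
}

#' Municipality-level metrics from producer predictions
#'
#' Maps true and predicted producer labels to municipalities and computes
#' metrics at municipality level. Since the mapping is a coarsening,
#' municipality accuracy is always at least the producer accuracy.
#'
#' @param y_true,y_pred producer label vectors.
#' @param mapping named vector producer -> municipality covering every
#'   producer appearing in either vector.
#' @return a `metrics_report` at municipality level.
#' @export
municipality_rollup <- function(y_true, y_pred, mapping) {
  labs <- unique(c(as.character(y_true), as.character(y_pred)))
  unmapped <- setdiff(labs, names(mapping))
  if (length(unmapped)) {
    stop("producer(s) without municipality mapping: ",
         paste(unmapped, collapse = ", "))
  }
  metrics(confusion(mapping[as.character(y_true)],
                    mapping[as.character(y_pred)]))
}

#' Per-visit performance table
#'
#' Computes balanced accuracy and weighted recall/precision/F1 independently
#' within each sampling visit.
#'
#' @param y_true,y_pred label vectors.
#' @param visits integer vector of sampling visits aligned with the labels.
#' @return data frame with one row per distinct visit, ordered by visit.
#' @export
temporal_table <- function(y_true, y_pred, visits) {
  stopifnot(length(visits) == length(y_true))
  out <- lapply(sort(unique(visits)), function(v) {
    sel <- visits == v
    if (!any(sel)) return(NULL)
    mt <- metrics(confusion(y_true[sel], y_pred[sel]))
    data.frame(visit = v,
               balanced_accuracy = mt$balanced_accuracy,
               weighted_recall = mt$weighted_recall,
               weighted_precision = mt$weighted_precision,
               weighted_f1 = mt$weighted_f1)
  })
  do.call(rbind, out)
}

# per-class F1 on a subset, over a fixed class list
.subset_f1 <- function(y_true, y_pred, sel, classes) {
  mt <- metrics(confusion(y_true[sel], y_pred[sel], classes))
  stats::setNames(mt$per_class$f1, mt$per_class$class)
}

#' Test-retest reliability between the two acquisition rounds
#'
#' Computes per-producer F1 separately on the round-1 and round-2 subsets of
#' the predictions and returns their Pearson correlation
#' `r12 = sum((f1 - mean(f1)) (f2 - mean(f2))) /
#' sqrt(sum((f1 - mean(f1))^2) sum((f2 - mean(f2))^2))`. A correlation near
#' 1 means the classifier ranks producers' difficulty consistently across
#' time-separated repeat acquisitions.
#'
#' @param y_true,y_pred producer label vectors (test images).
#' @param rounds integer vector in `{1, 2}` aligned with the labels.
#' @return a `reliability_report`: list with `f1_round1`, `f1_round2`
#'   (named per-producer vectors) and `r12`.
#' @export
test_retest <- function(y_true, y_pred, rounds) {
  y_true <- as.character(y_true)
  stopifnot(length(rounds) == length(y_true),
            length(y_pred) == length(y_true))
  if (!all(rounds %in% 1:2)) stop("rounds must be 1 or 2")
  classes <- sort(unique(y_true))
  if (length(classes) < 3L) stop("need at least 3 producers")
  for (r in 1:2) {
    missing <- setdiff(classes, unique(y_true[rounds == r]))
    if (length(missing)) {
      stop("producer(s) without images in round ", r, ": ",
           paste(missing, collapse = ", "))
    }
  }
  f1 <- .subset_f1(y_true, y_pred, rounds == 1L, classes)
  f2 <- .subset_f1(y_true, y_pred, rounds == 2L, classes)
  d1 <- f1 - mean(f1)
  d2 <- f2 - mean(f2)
  den <- sqrt(sum(d1^2) * sum(d2^2))
  if (den == 0) {
    stop("undefined correlation: per-producer F1 is constant in a round")
  }
  structure(
    list(f1_round1 = f1, f1_round2 = f2, r12 = sum(d1 * d2) / den),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("test-retest reliability r12 = %.4f over %d producers\n",
              x$r12, length(x$f1_round1)))
  invisible(x)
}

#' Write a metrics report to CSV
#'
#' Writes the per-class table with the aggregate metrics appended as
#' pseudo-rows.
#'
#' @param report a `metrics_report`.
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  agg <- data.frame(
    class = c("__accuracy__", "__balanced_accuracy__", "__macro_f1__",
              "__weighted_f1__"),
    precision = NA, recall = NA,
    f1 = c(report$accuracy, report$balanced_accuracy, report$macro_f1,
           report$weighted_f1),
    support = NA
  )
  utils::write.csv(rbind(report$per_class, agg), path, row.names = FALSE)
  invisible(path)
}
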