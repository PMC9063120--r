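# Metrics for imbalanced multi-target prediction: exact combination-class
# accuracy, micro-averaged precision/recall/F1 pooled over all targets,
# and average precision (AP) from soft per-target scores.

# Average precision of one target from soft scores; tie-safe (scores with
# equal value are grouped into one threshold). NA when the target has no
# positives.
average_precision <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth == 1)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  tp <- cumsum(y == 1)
  pred_pos <- seq_along(y)
  # threshold boundaries: last index of each distinct score value
  bound <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[bound] / pred_pos[bound]
  rec <- tp[bound] / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Score predictions against ground truth
#'
#' Computes the imbalance-aware metric panel: `accuracy` is the exact
#' combination-match rate (every target right); `micro_precision`,
#' `micro_recall` and `micro_f1` pool true/false positives across all
#' targets of all samples before forming ratios; `average_precision` is
#' computed per target from soft scores and macro-averaged (the per-target
#' values and the micro-pooled AP are also reported).
#'
#' @param predicted Binary matrix of decoded predictions (rows = samples,
#'   columns = targets).
#' @param truth Binary matrix of the same shape.
#' @param scores Optional numeric matrix of per-target soft scores (same
#'   shape) used for average precision.
#' @return A `gp_metrics` list.
#' @examples
#' score(matrix(c(1, 0, 1, 1), 2, byrow = TRUE),
#'       matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
#' @export
score <- function(predicted, truth, scores = NULL) {
  predicted <- as.matrix(predicted)
  truth <- as.matrix(truth)
  if (!all(dim(predicted) == dim(truth))) {
    stop("predicted and truth shapes differ: ",
         paste(dim(predicted), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
  }
  acc <- mean(rowSums(predicted != truth) == 0L)
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0

  ap_macro <- NA_real_
  ap_micro <- NA_real_
  ap_per_target <- NULL
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    stopifnot(all(dim(scores) == dim(truth)))
    ap_per_target <- vapply(seq_len(ncol(truth)), function(t) {
      average_precision(scores[, t], truth[, t])
    }, numeric(1L))
    ap_macro <- mean(ap_per_target, na.rm = TRUE)
    ap_micro <- average_precision(as.numeric(scores), as.numeric(truth))
  }

  structure(
    list(accuracy = acc, micro_precision = prec, micro_recall = rec,
         micro_f1 = f1, average_precision = ap_macro,
         average_precision_micro = ap_micro,
         average_precision_per_target = ap_per_target,
         counts = c(tp = tp, fp = fp, fn = fn)),
    class = "gp_metrics"
  )
}

#' @export
print.gp_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%%  micro P %.3f  R %.3f  F1 %.3f",
    100 * x$accuracy, x$micro_precision, x$micro_recall, x$micro_f1))
  if (!is.na(x$average_precision)) {
    cat(sprintf("  AP(macro) %.3f", x$average_precision))
  }
  cat("\n")
  invisible(x)
}

#' Aggregate metric reports over repeated runs
#'
#' Summarizes a list of [score()] reports as mean and sample standard
#' deviation per metric, with accuracy formatted as a percentage with two
#' decimals ("value +/- sd" style).
#'
#' @param reports List of `gp_metrics`.
#' @return Data frame with columns `metric`, `mean`, `sd` and `formatted`.
#' @export
aggregate_metrics <- function(reports) {
  stopifnot(length(reports) >= 1L)
  metrics <- c("accuracy", "micro_precision", "micro_recall", "micro_f1",
               "average_precision")
  rows <- lapply(metrics, function(m) {
    vals <- vapply(reports, function(r) r[[m]] %||% NA_real_, numeric(1L))
    mu <- mean(vals)
    sdv <- if (length(vals) > 1L) stats::sd(vals) else 0
    fmt <- if (m == "accuracy") {
      sprintf("%.2f ± %.2f", 100 * mu, 100 * sdv)
    } else {
      sprintf("%.2f ± %.2f", mu, sdv)
    }
    data.frame(metric = m, mean = mu, sd = sdv, formatted = fmt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
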