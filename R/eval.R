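#' Local confusion counts
#'
#' The confusion matrix is a summable sufficient statistic for
#' classification metrics: parties share only counts, never labels, and
#' the aggregated matrix equals the confusion of the pooled predictions.
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param labels Ordered label set; defaults to the sorted union observed.
#' @return Object of class `confusion_counts`: `labels`, integer `counts`
#'   matrix (true x predicted), `n`.
#' @export
confusion_counts <- function(truth, pred, labels = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  if (is.null(labels)) labels <- sort(unique(c(truth, pred)))
  m <- table(factor(truth, levels = labels), factor(pred, levels = labels))
  structure(
    list(labels = labels,
         counts = matrix(as.integer(m), nrow = length(labels),
                         dimnames = list(truth = labels, pred = labels)),
         n = length(truth)),
    class = "confusion_counts"
  )
}

#' Aggregate per-party confusion counts
#'
#' The coordinator unions the label sets, reindexes each matrix onto the
#' global ordering, and sums elementwise.
#'
#' @param cms List of [confusion_counts()] objects.
#' @return A `confusion_counts` over the unioned label set.
#' @export
aggregate_confusion <- function(cms) {
  stopifnot(length(cms) >= 1)
  labels <- sort(unique(unlist(lapply(cms, function(cm) cm$labels))))
  k <- length(labels)
  total <- matrix(0L, k, k, dimnames = list(truth = labels, pred = labels))
  for (cm in cms) {
    total[cm$labels, cm$labels] <- total[cm$labels, cm$labels] + cm$counts
  }
  structure(list(labels = labels, counts = total, n = sum(total)),
            class = "confusion_counts")
}

#' F1 score from a confusion matrix
#'
#' Binary positive-class F1 by default (`2 TP / (2 TP + FP + FN)`, defined
#' as 0 when the denominator vanishes); `average = "macro"` returns the
#' unweighted mean of per-class F1 scores.
#'
#' @param cm A [confusion_counts()] object.
#' @param positive Positive class label (binary mode).
#' @param average `"binary"` or `"macro"`.
#' @return F1 in `[0, 1]`.
#' @export
f1_from_confusion <- function(cm, positive = NULL,
                              average = c("binary", "macro")) {
  average <- match.arg(average)
  one_f1 <- function(lab) {
    tp <- cm$counts[lab, lab]
    fp <- sum(cm$counts[, lab]) - tp
    fn <- sum(cm$counts[lab, ]) - tp
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }
  if (average == "macro") {
    return(mean(vapply(cm$labels, one_f1, numeric(1))))
  }
  if (is.null(positive)) positive <- cm$labels[length(cm$labels)]
  if (!positive %in% cm$labels) {
    stop("positive label not present in label set", call. = FALSE)
  }
  one_f1(positive)
}

#' Local squared- and absolute-error sums
#'
#' Regression metrics federate through `(n, SSE, SAE)`: summing them over
#' parties and finishing the metric centrally equals computing it on the
#' pooled predictions.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Object of class `error_sums`: `n`, `sse`, `sae`.
#' @export
error_sums <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  structure(
    list(n = length(y), sse = sum((y - yhat)^2), sae = sum(abs(y - yhat))),
    class = "error_sums"
  )
}

#' Aggregate per-party error sums
#'
#' @param es_list List of [error_sums()] objects.
#' @return An `error_sums` with summed components.
#' @export
aggregate_error_sums <- function(es_list) {
  stopifnot(length(es_list) >= 1)
  structure(
    list(n = sum(vapply(es_list, function(e) e$n, numeric(1))),
         sse = sum(vapply(es_list, function(e) e$sse, numeric(1))),
         sae = sum(vapply(es_list, function(e) e$sae, numeric(1)))),
    class = "error_sums"
  )
}

#' RMSE (and MAE) from aggregated error sums
#'
#' @param es An [error_sums()] object.
#' @return `rmse_from_sums()` returns `sqrt(sse / n)`; `mae_from_sums()`
#'   returns `sae / n`.
#' @export
rmse_from_sums <- function(es) {
  stopifnot(es$n >= 1)
  sqrt(es$sse / es$n)
}

#' @rdname rmse_from_sums
#' @export
mae_from_sums <- function(es) {
  stopifnot(es$n >= 1)
  es$sae / es$n
}

#' Summarize per-fold metrics across a cross-validation
#'
#' Produces the distribution summary used to compare centralized,
#' federated, and local-only models: per-fold values plus median and
#' quartiles (Tukey-style box-plot statistics).
#'
#' @param per_fold_metrics Named or unnamed numeric vector of per-fold
#'   metric values, or a data frame with columns `fold` and `metric`.
#' @param metric_name Label for the metric (e.g. `"f1"`, `"rmse"`).
#' @return Object of class `fed_cv_report`: list with tibbles `per_fold`
#'   and `summary` (`median`, `q1`, `q3`, `min`, `max`, `n_folds`).
#' @export
cv_report <- function(per_fold_metrics, metric_name = "metric") {
  if (is.data.frame(per_fold_metrics)) {
    per_fold <- tibble::tibble(
      fold = per_fold_metrics$fold,
      metric = per_fold_metrics$metric
    )
  } else {
    per_fold <- tibble::tibble(
      fold = seq_along(per_fold_metrics),
      metric = as.numeric(per_fold_metrics)
    )
  }
  stopifnot(nrow(per_fold) >= 1)
  q <- stats::quantile(per_fold$metric, c(0.25, 0.5, 0.75), names = FALSE)
  structure(
    list(
      metric_name = metric_name,
      per_fold = per_fold,
      summary = tibble::tibble(
        metric = metric_name,
        median = q[2], q1 = q[1], q3 = q[3],
        min = min(per_fold$metric), max = max(per_fold$metric),
        n_folds = nrow(per_fold)
      )
    ),
    class = "fed_cv_report"
  )
}

#' @export
print.fed_cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation report: %s over %d fold(s)\n",
              x$metric_name, nrow(x$per_fold)))
  print(x$summary)
  invisible(x)
}
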