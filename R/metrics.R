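## One-vs-rest multiclass metrics.
##
## Each class c is scored against the 2x2 table obtained by collapsing the
## six-class confusion matrix (TP, FP, FN, TN). All metrics are reported on
## the percent scale, including MCC (x100), matching the conventional
## tabulation; per-class "accuracy" is the one-vs-rest (TP+TN)/total. Macro
## averages are unweighted arithmetic means across classes.

#' Multiclass confusion matrix
#'
#' `counts[t, p]` is the number of samples with true class `t` predicted as
#' class `p`; rows and columns follow `classes` order.
#'
#' @param truth,predicted equal-length label vectors (values in `classes`).
#' @param classes class order (default the six-class taxonomy).
#' @return k x k integer matrix with dimnames `truth` x `predicted`.
#' @export
confusionMatrix <- function(truth, predicted, classes = classNames()) {
  stopIfNot(length(truth) == length(predicted),
            "truth and predicted lengths differ")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Per-class one-vs-rest metrics
#'
#' For each class: `accuracy = 100 (TP+TN)/total`, `precision = 100 TP/(TP+FP)`,
#' `recall = 100 TP/(TP+FN)`, `specificity = 100 TN/(TN+FP)`,
#' `f_score = 2 P R / (P + R)` (already on the percent scale), and
#' `mcc = 100 (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero denominator yields 0 with a warning.
#'
#' @param cm confusion matrix from [confusionMatrix()].
#' @return data.frame, one row per class, columns `class`, `accuracy`,
#'   `precision`, `recall`, `specificity`, `f_score`, `mcc`.
#' @export
perClassMetrics <- function(cm) {
  total <- sum(cm)
  stopIfNot(total > 0, "empty confusion matrix")
  safeDiv <- function(num, den, what) {
    if (den == 0) { warning("zero denominator in ", what, "; reporting 0"); 0 }
    else num / den
  }
  out <- lapply(seq_len(nrow(cm)), function(c) {
    tp <- cm[c, c]
    fp <- sum(cm[-c, c])
    fn <- sum(cm[c, -c])
    tn <- total - tp - fp - fn
    prec <- 100 * safeDiv(tp, tp + fp, "precision")
    rec <- 100 * safeDiv(tp, tp + fn, "recall")
    mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    data.frame(
      class = rownames(cm)[c],
      accuracy = 100 * (tp + tn) / total,
      precision = prec,
      recall = rec,
      specificity = 100 * safeDiv(tn, tn + fp, "specificity"),
      f_score = safeDiv(2 * prec * rec, prec + rec, "f_score"),
      mcc = 100 * safeDiv(tp * tn - fp * fn,
                          if (mccDen == 0) 0 else mccDen, "mcc"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Macro (unweighted) average of per-class metrics
#'
#' @param perClass data.frame from [perClassMetrics()] (or any data.frame of
#'   numeric metric columns).
#' @return one-row data.frame with the arithmetic mean of each numeric column.
#' @export
macroAverage <- function(perClass) {
  stopIfNot(nrow(perClass) > 0, "empty metric table")
  num <- vapply(perClass, is.numeric, TRUE)
  res <- as.data.frame(lapply(perClass[num], mean))
  cbind(data.frame(class = "average", stringsAsFactors = FALSE), res)
}

# Two-decimal half-up formatting used in reports.
formatMetric <- function(x) sprintf("%.2f", roundHalfUp(x * 100) / 100)

#' Structured metrics report
#'
#' Per-class blocks plus the macro-average block, suitable for JSON export
#' (the macro recall is also exposed under the alias `sensitivity`, a common
#' alternative name for the same quantity).
#'
#' @param cm confusion matrix from [confusionMatrix()].
#' @return list with `per_class`, `average`, and `confusion` components.
#' @export
metricsReport <- function(cm) {
  pc <- perClassMetrics(cm)
  avg <- macroAverage(pc)
  list(
    per_class = pc,
    average = c(as.list(avg[-1]), sensitivity = avg$recall),
    confusion = cm
  )
}

#' Write a metrics report as JSON and the confusion matrix as CSV
#'
#' @param report list from [metricsReport()].
#' @param jsonPath,csvPath output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
writeMetricsReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  if (!is.null(jsonPath)) {
    payload <- list(schema = "nutrivision-metrics-1",
                    per_class = report$per_class,
                    average = report$average)
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(csvPath)) {
    write.csv(as.data.frame(report$confusion[, , drop = FALSE]), csvPath)
  }
  invisible(report)
}
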