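# Episode-level evaluation: 2x2 confusion matrix (rows = actual,
# columns = predicted), accuracy/precision/recall, and the
# model-comparison report.

#' Build a confusion matrix from label vectors
#'
#' Orientation is fixed: rows = actual, columns = predicted, with the
#' chosen positive class first.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive_class The positive class label; default `"medication"`.
#' @return A [ConfusionMatrix-class].
#' @examples
#' cm <- confusion(c("medication", "non_medication"),
#'                 c("medication", "medication"))
#' cm
#' @export
confusion <- function(y_true, y_pred, positive_class = "medication") {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  pos_t <- y_true == positive_class
  pos_p <- y_pred == positive_class
  neg <- setdiff(unique(c(y_true, y_pred)), positive_class)
  negative_class <- if (length(neg)) neg[1] else "other"
  new("ConfusionMatrix",
      tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
      fp = sum(!pos_t & pos_p), tn = sum(!pos_t & !pos_p),
      positiveClass = positive_class, negativeClass = negative_class)
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fn,fp,tn Cell counts (rows = actual, columns = predicted).
#' @param positive_class,negative_class Class labels.
#' @return A [ConfusionMatrix-class].
#' @export
confusionFromCounts <- function(tp, fn, fp, tn,
                                positive_class = "medication",
                                negative_class = "non_medication") {
  new("ConfusionMatrix", tp = tp, fn = fn, fp = fp, tn = tn,
      positiveClass = positive_class, negativeClass = negative_class)
}

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              byrow = TRUE,
              dimnames = list(actual = c(object@positiveClass,
                                         object@negativeClass),
                              predicted = c(object@positiveClass,
                                            object@negativeClass)))
  cat("ConfusionMatrix (rows = actual, columns = predicted)\n")
  print(m)
})

#' Convert a confusion matrix to a 2x2 count matrix
#' @param cm A [ConfusionMatrix-class].
#' @return A 2x2 numeric matrix, rows = actual, columns = predicted.
#' @export
confusionCounts <- function(cm) {
  matrix(c(cm@tp, cm@fn, cm@fp, cm@tn), 2, 2, byrow = TRUE,
         dimnames = list(actual = c(cm@positiveClass, cm@negativeClass),
                         predicted = c(cm@positiveClass, cm@negativeClass)))
}

#' Accuracy, precision and recall from a confusion matrix
#'
#' `accuracy = (tp+tn)/total`, `precision = tp/(tp+fp)`,
#' `recall = tp/(tp+fn)`. A zero denominator yields 0 with a warning.
#'
#' @param cm A [ConfusionMatrix-class] with at least one count.
#' @return List with `accuracy`, `precision`, `recall`, `n_total`.
#' @examples
#' classMetrics(confusionFromCounts(50, 5, 3, 52))
#' @export
classMetrics <- function(cm) {
  total <- cm@tp + cm@fn + cm@fp + cm@tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0",
              call. = FALSE)
      0
    } else num / den
  }
  list(accuracy = (cm@tp + cm@tn) / total,
       precision = safeDiv(cm@tp, cm@tp + cm@fp, "precision"),
       recall = safeDiv(cm@tp, cm@tp + cm@fn, "recall"),
       n_total = total)
}

#' Model-comparison report
#'
#' One row per model with accuracy, precision and recall on the same test
#' set. Models are given as a named list of predicted label vectors (all
#' evaluated against the same `y_true`).
#'
#' @param predictions Named list of predicted label vectors.
#' @param y_true True labels.
#' @param positive_class Positive class label.
#' @param digits Rounding for the report (default 3, matching the
#'   conventional presentation); use `NA` for no rounding.
#' @return Data frame with `method`, `accuracy`, `precision`, `recall`.
#' @export
comparisonReport <- function(predictions, y_true,
                             positive_class = "medication", digits = 3) {
  rows <- lapply(names(predictions), function(nm) {
    m <- classMetrics(confusion(y_true, predictions[[nm]], positive_class))
    data.frame(method = nm, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.na(digits)) {
    for (col in c("accuracy", "precision", "recall")) {
      out[[col]] <- round(out[[col]], digits)
    }
  }
  out
}

#' Write a confusion matrix as a 2x2 CSV
#'
#' @param cm A [ConfusionMatrix-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeConfusionCSV <- function(cm, path) {
  m <- confusionCounts(cm)
  df <- data.frame(actual = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
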