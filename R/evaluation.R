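#' Confusion counts for binary fall detection
#'
#' Tallies true/false positives and negatives from aligned predicted and true
#' labels, with `"fall"` as the positive class throughout the package.
#'
#' @param pred Character vector of predicted labels, `"fall"` or `"notfall"`.
#' @param truth Character vector of true labels, same length as `pred`.
#' @param level Either `"frame"` or `"video"`; recorded on the result so
#'   downstream reports can state at which granularity the counts were taken.
#' @return An object of class `confusion_counts`: a list with integer fields
#'   `tp`, `fp`, `tn`, `fn`, the `total`, and the `level`.
#' @examples
#' confusion(c("fall", "notfall"), c("fall", "fall"))
#' @export
confusion <- function(pred, truth, level = c("video", "frame")) {
  level <- match.arg(level)
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must be aligned vectors of equal length (got ",
         length(pred), " and ", length(truth), ")")
  }
  pred <- as_fall_label(pred)
  truth <- as_fall_label(truth)
  counts <- list(
    tp = sum(pred == "fall" & truth == "fall"),
    fp = sum(pred == "fall" & truth == "notfall"),
    tn = sum(pred == "notfall" & truth == "notfall"),
    fn = sum(pred == "notfall" & truth == "fall")
  )
  counts$total <- counts$tp + counts$fp + counts$tn + counts$fn
  counts$level <- level
  structure(counts, class = "confusion_counts")
}

#' Build confusion counts directly from tallies
#'
#' Convenience constructor for recomputing published metric tables from their
#' printed TP/FP/TN/FN entries.
#'
#' @param tp,fp,tn,fn Non-negative event counts.
#' @inheritParams confusion
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn, level = c("video", "frame")) {
  level <- match.arg(level)
  for (v in c(tp, fp, tn, fn)) {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
      stop("counts must be single non-negative integers")
    }
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 total = tp + fp + tn + fn, level = level),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (%s level): TP=%d FP=%d TN=%d FN=%d total=%d\n",
              x$level, x$tp, x$fp, x$tn, x$fn, x$total))
  invisible(x)
}

# Normalize label spellings; errors on anything outside the two classes.
as_fall_label <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("not-fall", "not_fall", "nonfall", "non-fall", "no_fall")] <- "notfall"
  bad <- setdiff(unique(x), c("fall", "notfall"))
  if (length(bad) > 0) {
    stop("labels must be 'fall' or 'notfall'; got: ", paste(bad, collapse = ", "))
  }
  x
}

#' Five classification metrics from confusion counts
#'
#' Computes sensitivity, specificity, accuracy, precision and F1-score as
#' percentages. Sensitivity is TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total, precision TP/(TP+FP), and F1 = 2TP/(2TP+FP+FN). A metric
#' whose denominator is zero is reported as `NA` (flagged, never silently 0).
#'
#' @param counts A `confusion_counts` object with `total > 0`.
#' @return A `metric_set` object: named list of the five percentages at full
#'   precision plus a `display` character vector rounded half-up to 2 decimals.
#' @examples
#' metrics(confusion_counts(tp = 98, fp = 0, tn = 120, fn = 22))
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$total <= 0) stop("cannot compute metrics on zero events")
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  m <- list(
    sensitivity = frac(counts$tp, counts$tp + counts$fn),
    specificity = frac(counts$tn, counts$tn + counts$fp),
    accuracy    = frac(counts$tp + counts$tn, counts$total),
    precision   = frac(counts$tp, counts$tp + counts$fp),
    f1          = frac(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn)
  )
  m$display <- vapply(m[1:5], function(v) {
    if (is.na(v)) "undefined" else sprintf("%.2f%%", round_half_up(v, 2))
  }, character(1))
  structure(m, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  lab <- c("Sensitivity", "Specificity", "Accuracy", "Precision", "F1-score")
  for (i in seq_along(lab)) cat(sprintf("%-12s %s\n", lab[i], x$display[i]))
  invisible(x)
}

# Half-up decimal rounding (base round() is round-half-even, which does not
# reproduce the conventional printed tables at .xx5 boundaries).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
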