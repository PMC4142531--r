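#' Normalization evaluation metrics
#'
#' Precision, recall and F-measure over annotated confusion counts:
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`. Metrics are
#' reported as percentages rounded half-up to one decimal at output
#' only; F is computed from the unrounded P and R.
#'
#' @name eval_metrics
NULL

#' Confusion counts
#'
#' @param tp,fp,fn non-negative integer counts of true positives, false
#'   positives and false negatives
#' @return object of class `confusion_counts`
#' @export
confusion_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

precision_raw <- function(c) {
  if (c$tp + c$fp == 0L) {
    stop_aersdm("precision undefined: no predictions (TP+FP = 0)",
                "aersdm_undefined_metric")
  }
  c$tp / (c$tp + c$fp)
}

recall_raw <- function(c) {
  if (c$tp + c$fn == 0L) {
    stop_aersdm("recall undefined: no gold positives (TP+FN = 0)",
                "aersdm_undefined_metric")
  }
  c$tp / (c$tp + c$fn)
}

#' @rdname eval_metrics
#' @param c a `confusion_counts` object
#' @return percentage rounded half-up to one decimal
#' @export
#' @examples
#' precision(confusion_counts(138, 7, 6))  # 95.2
precision <- function(c) round_half_up(100 * precision_raw(c), 1)

#' @rdname eval_metrics
#' @export
#' @examples
#' recall(confusion_counts(138, 7, 6))  # 95.8
recall <- function(c) round_half_up(100 * recall_raw(c), 1)

#' @rdname eval_metrics
#' @export
#' @examples
#' f_measure(confusion_counts(138, 7, 6))  # 95.5
f_measure <- function(c) {
  p <- precision_raw(c)
  r <- recall_raw(c)
  if (p + r == 0) return(0)
  round_half_up(100 * 2 * p * r / (p + r), 1)
}

#' Score predicted mentions against a gold standard
#'
#' Gold is a map from input string to the reviewer-assigned rxcui
#' (`NA` = reviewers assigned no code). A prediction agreeing with gold
#' is a TP; a prediction with a code where gold differs or has no code
#' is an FP — and when gold had a code that was thereby missed, also an
#' FN; a gold-coded string the system left unmatched is an FN.
#'
#' @param predicted mention table with columns `input_string`, `rxcui`,
#'   `status`
#' @param gold `data.table`/data.frame with columns `input_string`,
#'   `rxcui` (`NA` where no code applies)
#' @return a `confusion_counts`
#' @export
score_against_gold <- function(predicted, gold) {
  predicted <- unique(data.table::as.data.table(predicted),
                      by = "input_string")
  gold <- unique(data.table::as.data.table(gold), by = "input_string")
  m <- merge(gold[, list(input_string, gold_rxcui = rxcui)],
             predicted[, list(input_string, pred_rxcui = rxcui, status)],
             by = "input_string", all.x = TRUE)
  pred_has <- !is.na(m$pred_rxcui)
  gold_has <- !is.na(m$gold_rxcui)
  tp <- sum(pred_has & gold_has & m$pred_rxcui == m$gold_rxcui)
  fp <- sum(pred_has & (!gold_has | m$pred_rxcui != m$gold_rxcui))
  fn <- sum(gold_has & (!pred_has | m$pred_rxcui != m$gold_rxcui))
  confusion_counts(tp, fp, fn)
}
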