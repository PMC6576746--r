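#' Binding truth labels from a kinome competition panel
#'
#' A kinase is called a true off-target when its percent control at the high
#' assay dose (100 uM) falls strictly below the threshold (default 30.0) —
#' lower percent control means stronger displacement, hence binding.
#'
#' @param records Data.frame with columns `kinase`, `pct_control_100uM`
#'   (and typically `pct_control_10uM`, unused here).
#' @param threshold Percent-control cutoff, strict (default 30.0).
#' @return Named logical vector: `TRUE` = positive (binder).
#' @examples
#' truth_from_kinome(data.frame(kinase = c("RIOK1", "X"),
#'                              pct_control_100uM = c(0, 30)))
#' @export
truth_from_kinome <- function(records, threshold = 30.0) {
  stopifnot(is.data.frame(records),
            all(c("kinase", "pct_control_100uM") %in% names(records)))
  if (any(!is.finite(records$pct_control_100uM) |
          records$pct_control_100uM < 0))
    stop("percent control values must be finite and >= 0")
  stats::setNames(records$pct_control_100uM < threshold,
                  as.character(records$kinase))
}

#' Top-k% prediction cut
#'
#' Flags the `ceiling(fraction * panel_size)` highest-ranked predictions as
#' positive. With the 2.5% cut on a 452-kinase panel this yields k = 12.
#'
#' @param ranked Character vector of panel members in descending prediction
#'   order (or a data.frame whose first column is taken).
#' @param fraction Fraction flagged positive, in (0, 1); default 0.025.
#' @param panel_size Size of the panel (default `length(ranked)`).
#' @return Character vector: the predicted-positive set (first k of
#'   `ranked`).
#' @export
topk_cut <- function(ranked, fraction = 0.025, panel_size = NULL) {
  if (is.data.frame(ranked)) ranked <- ranked[[1]]
  if (is.null(panel_size)) panel_size <- length(ranked)
  if (!(fraction > 0 && fraction < 1))
    stop("'fraction' must lie in (0, 1)")
  k <- ceiling(fraction * panel_size)
  if (k < 1) stop("top-k cut selects zero predictions")
  utils::head(ranked, k)
}

#' Confusion counts against panel truth
#'
#' @param predicted Character vector of predicted-positive panel members.
#' @param truth Named logical vector over the full panel (from
#'   [truth_from_kinome()]).
#' @return Object of class `confusion_counts`: integer vector with elements
#'   `tp`, `fp`, `tn`, `fn` (summing to the panel size).
#' @export
confusion <- function(predicted, truth) {
  stopifnot(is.logical(truth), !is.null(names(truth)))
  predicted <- unique(as.character(predicted))
  outside <- setdiff(predicted, names(truth))
  if (length(outside))
    stop("prediction(s) outside the panel: ", paste(outside, collapse = ", "))
  pred <- names(truth) %in% predicted
  counts <- c(tp = sum(pred & truth), fp = sum(pred & !truth),
              tn = sum(!pred & !truth), fn = sum(!pred & truth))
  structure(as.integer(counts), names = names(counts),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP = %d, FP = %d, TN = %d, FN = %d (panel of %d)\n",
              x[["tp"]], x[["fp"]], x[["tn"]], x[["fn"]], sum(x)))
  invisible(x)
}

#' Precision, recall and false-positive rate (in percent)
#'
#' `precision = TP/(TP+FP) * 100`, `recall = TP/(TP+FN) * 100`,
#' `FPR = FP/(FP+TN) * 100`. A zero denominator yields 0 with the
#' `undefined` attribute flagging which metrics it affected (matching the
#' 0-entries of panel evaluations where no true positive is retrieved).
#'
#' @param counts A `confusion_counts` object, or `tp` given all four counts
#'   separately.
#' @param fp,tn,fn Individual counts when `counts` is the scalar `tp`.
#' @return Named numeric vector `(precision, recall, fpr)` in percent, with
#'   attribute `undefined` naming zero-denominator metrics (if any).
#' @examples
#' precision_recall_fpr(4, 8, 408, 32)  # 33.3, 11.1, 1.92 at 3 sig. figures
#' @export
precision_recall_fpr <- function(counts, fp = NULL, tn = NULL, fn = NULL) {
  if (inherits(counts, "confusion_counts") ||
      (is.numeric(counts) && length(counts) == 4 && is.null(fp))) {
    if (is.null(names(counts))) names(counts) <- c("tp", "fp", "tn", "fn")
    tp <- counts[["tp"]]; fp <- counts[["fp"]]
    tn <- counts[["tn"]]; fn <- counts[["fn"]]
  } else {
    tp <- counts
  }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0) stop("all counts are zero")
  undef <- character(0)
  div <- function(num, den, what) {
    if (den == 0) { undef <<- c(undef, what); return(0) }
    num / den * 100
  }
  out <- c(precision = div(tp, tp + fp, "precision"),
           recall = div(tp, tp + fn, "recall"),
           fpr = div(fp, fp + tn, "fpr"))
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' Evaluate a ranked prediction list against a kinome panel
#'
#' The fixed-cut evaluation protocol: truth labels from the panel percent
#' controls (strict < 30 at 100 uM), top-k% of the ranking flagged positive
#' (k = ceiling of 2.5% of the panel), then confusion counts and
#' precision/recall/FPR.
#'
#' @param ranked Panel members in descending prediction order.
#' @param records Kinome assay data.frame (see [truth_from_kinome()]).
#' @param fraction Top fraction flagged positive (default 0.025).
#' @param threshold Percent-control truth threshold (default 30.0).
#' @return One-row data.frame with columns `tp`, `fp`, `tn`, `fn`,
#'   `precision`, `recall`, `fpr` (percent, full precision; round for
#'   display with [signif()]).
#' @export
evaluate_panel <- function(ranked, records, fraction = 0.025,
                           threshold = 30.0) {
  truth <- truth_from_kinome(records, threshold)
  missing_truth <- setdiff(as.character(if (is.data.frame(ranked)) ranked[[1]] else ranked),
                           names(truth))
  if (length(missing_truth))
    stop("ranked member(s) without truth: ",
         paste(utils::head(missing_truth, 5), collapse = ", "))
  pred <- topk_cut(ranked, fraction, panel_size = length(truth))
  cc <- confusion(pred, truth)
  met <- precision_recall_fpr(cc)
  data.frame(tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]],
             fn = cc[["fn"]], precision = met[["precision"]],
             recall = met[["recall"]], fpr = met[["fpr"]])
}
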