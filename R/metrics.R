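# Beat-by-beat evaluation: greedy one-to-one matching of detections against
# reference annotations, and the five ratio metrics computed from the
# resulting TP/FP/FN/TN counts.

#' Construct confusion counts
#'
#' For beat detection there is no defined negative event, so `tn` is 0 by
#' convention and specificity/accuracy are meaningful mainly for
#' classification tasks.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `"confusion_counts"`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || anyNA(v)) stop("confusion counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Match detected beats against reference annotations
#'
#' Greedy nearest-neighbour one-to-one matching within a time tolerance:
#' candidate pairs are ranked by absolute time difference (ties: earlier
#' reference first, then earlier detection) and assigned greedily. Matched
#' pairs count as TP, unmatched detections as FP, unmatched references as
#' FN; TN is 0 by the detection convention.
#'
#' @param detected Integer vector of detected R-peak indices (or a
#'   `"qrs_detection"` object).
#' @param reference Integer vector of reference beat indices (or a
#'   [beat_annotations()] object).
#' @param fs Sampling frequency in Hz.
#' @param tolerance_ms Matching tolerance; default 50 ms (use 150 for the
#'   AAMI convention).
#' @return A [confusion_counts()] object with attribute `pairs`, an integer
#'   matrix of the matched (detected, reference) index pairs.
#' @export
match_beats <- function(detected, reference, fs, tolerance_ms = 50) {
  if (inherits(detected, "qrs_detection")) detected <- detected$rlocs
  if (inherits(reference, "beat_annotations")) reference <- reference$index
  detected <- as.integer(detected)
  reference <- as.integer(reference)
  stopifnot(!is.unsorted(detected), !is.unsorted(reference))
  tol <- tolerance_ms / 1000 * fs
  cand <- NULL
  if (length(detected) && length(reference)) {
    cand <- do.call(rbind, lapply(seq_along(detected), function(i) {
      dt <- abs(reference - detected[i])
      j <- which(dt <= tol)
      if (length(j)) cbind(det = i, ref = j, adist = dt[j]) else NULL
    }))
  }
  tp_pairs <- matrix(integer(0), ncol = 2,
                     dimnames = list(NULL, c("det", "ref")))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand[, "adist"], cand[, "ref"], cand[, "det"]), ,
                 drop = FALSE]
    used_d <- logical(length(detected))
    used_r <- logical(length(reference))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, "det"]; j <- cand[k, "ref"]
      if (!used_d[i] && !used_r[j]) {
        used_d[i] <- TRUE
        used_r[j] <- TRUE
        keep[k] <- TRUE
      }
    }
    tp_pairs <- cbind(det = cand[keep, "det"], ref = cand[keep, "ref"])
  }
  tp <- nrow(tp_pairs)
  out <- confusion_counts(tp = tp, fp = length(detected) - tp,
                          fn = length(reference) - tp, tn = 0)
  attr(out, "pairs") <- tp_pairs
  out
}

.pct <- function(num, den, what) {
  if (den <= 0) {
    message(what, " undefined (zero denominator); reported as NA")
    return(NA_real_)
  }
  100 * num / den
}

#' Sensitivity (Se)
#'
#' `100 * TP / (TP + FN)`: the percentage of true beats detected.
#'
#' @param c A [confusion_counts()] object.
#' @return Percentage, or `NA` when undefined.
#' @export
sensitivity <- function(c) .pct(c$tp, c$tp + c$fn, "sensitivity")

#' Positive predictivity (+P)
#'
#' `100 * TP / (TP + FP)`: the percentage of detections that are true beats.
#'
#' @inheritParams sensitivity
#' @return Percentage, or `NA` when undefined.
#' @export
positive_predictivity <- function(c) .pct(c$tp, c$tp + c$fp, "+P")

#' Detection error rate (DER)
#'
#' `100 * (FP + FN) / TP`: combined false-alarm and miss rate relative to
#' the true positives. Can exceed 100.
#'
#' @inheritParams sensitivity
#' @return Percentage, or `NA` when TP is 0.
#' @export
detection_error_rate <- function(c) .pct(c$fp + c$fn, c$tp, "DER")

#' Specificity
#'
#' Two variants are provided. `"ratio"` (default) is `100 * TN / (TP + FP)`
#' exactly as tabulated in the detection literature this chain follows; it
#' is not the usual definition and a note is emitted once per call.
#' `"standard"` is the conventional `100 * TN / (TN + FP)`.
#'
#' @inheritParams sensitivity
#' @param variant `"ratio"` or `"standard"`.
#' @return Percentage, or `NA` when undefined.
#' @export
specificity <- function(c, variant = c("ratio", "standard")) {
  variant <- match.arg(variant)
  if (variant == "ratio") {
    message("specificity variant 'ratio' = 100*TN/(TP+FP); ",
            "use variant = 'standard' for TN/(TN+FP)")
    .pct(c$tn, c$tp + c$fp, "specificity")
  } else {
    .pct(c$tn, c$tn + c$fp, "specificity")
  }
}

#' Accuracy
#'
#' `100 * (TP + TN) / (TP + FP + TN + FN)`.
#'
#' @inheritParams sensitivity
#' @return Percentage, or `NA` when all counts are 0.
#' @export
accuracy <- function(c) .pct(c$tp + c$tn, c$tp + c$fp + c$tn + c$fn, "accuracy")

#' Build a per-record detection report
#'
#' One row in the beat-detection table layout: record id, total beats (TB),
#' detected beats (DB), TP/FP/FN and the Se, +P and DER percentages.
#'
#' @param record_id Record label.
#' @param reference Reference beat indices or [beat_annotations()].
#' @param detected Detected indices or a `"qrs_detection"` object.
#' @param fs Sampling frequency in Hz.
#' @param tolerance_ms Matching tolerance in ms.
#' @return A one-row data frame of class `"detection_report"` with columns
#'   `record_id`, `tb`, `db`, `tp`, `fp`, `fn`, `se`, `pp`, `der`
#'   (percentages at full precision; see [format_detection_report()]).
#' @export
detection_report <- function(record_id, reference, detected, fs,
                             tolerance_ms = 50) {
  if (inherits(detected, "qrs_detection")) detected <- detected$rlocs
  if (inherits(reference, "beat_annotations")) reference <- reference$index
  cc <- match_beats(detected, reference, fs, tolerance_ms)
  out <- data.frame(record_id = as.character(record_id),
                    tb = length(reference), db = length(detected),
                    tp = cc$tp, fp = cc$fp, fn = cc$fn,
                    se = sensitivity(cc), pp = positive_predictivity(cc),
                    der = detection_error_rate(cc))
  class(out) <- c("detection_report", "data.frame")
  out
}

#' Format a detection report at two decimals
#'
#' @param report A `"detection_report"` (rows may be rbind-ed).
#' @param style `"round"` (half-up) or `"truncate"` (toward zero) applied to
#'   the percentage columns.
#' @return A data frame with `se`, `pp`, `der` as two-decimal character
#'   columns.
#' @export
format_detection_report <- function(report, style = c("round", "truncate")) {
  style <- match.arg(style)
  fmt <- function(x) {
    y <- if (style == "truncate") trunc(x * 100) / 100 else
      floor(x * 100 + 0.5) / 100
    ifelse(is.na(x), "", sprintf("%.2f", y))
  }
  out <- as.data.frame(report)
  for (col in c("se", "pp", "der")) out[[col]] <- fmt(out[[col]])
  out
}
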