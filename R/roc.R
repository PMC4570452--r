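# ROC-area screening of single-feature discriminability --------------------

#' ROC area of one feature against the alert/drowsy labels
#'
#' The raw area under the ROC curve equals the normalised Mann-Whitney U
#' statistic of the positive-class (+1, slightly drowsy) scores against the
#' negative-class (-1, alert) scores, with tied cross-class pairs counting
#' one half; it is computed here from midranks. Because a feature may
#' discriminate in either direction (theta power *falls* with drowsiness),
#' the headline `auc` is folded to `max(raw_auc, 1 - raw_auc)`, so it lies
#' in `[0.5, 1]`; the raw value and the orientation used are reported
#' alongside, and the curve points are computed in the discriminating
#' orientation.
#'
#' @param scores numeric feature values, one per window.
#' @param labels integer labels in `{-1, +1}`; both classes required.
#' @return A `ddd_roc` list: `raw_auc`, `auc`, `orientation` (`"as-is"` or
#'   `"reversed"`), and `curve` (threshold, sensitivity, 1 - specificity).
#' @export
roc_area <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  if (!all(labels %in% c(-1L, 1L)))
    stop("roc contract error: labels must be -1/+1", call. = FALSE)
  pos <- labels == 1L
  n_p <- sum(pos); n_n <- sum(!pos)
  if (n_p == 0 || n_n == 0)
    stop("roc contract error: both classes must be present", call. = FALSE)
  r <- rank(scores)                      # midranks handle ties as 1/2
  raw <- (sum(r[pos]) - n_p * (n_p + 1) / 2) / (n_p * n_n)
  orientation <- if (raw >= 0.5) "as-is" else "reversed"
  s <- if (orientation == "as-is") scores else -scores
  thr <- sort(unique(s), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    sensitivity = c(0, vapply(thr, function(t) mean(s[pos] >= t), 0)),
    fpr = c(0, vapply(thr, function(t) mean(s[!pos] >= t), 0)))
  structure(list(raw_auc = raw, auc = max(raw, 1 - raw),
                 orientation = orientation, curve = curve,
                 n_pos = n_p, n_neg = n_n),
            class = "ddd_roc")
}

#' @export
print.ddd_roc <- function(x, ...) {
  cat(sprintf("<ddd_roc auc = %.3f (raw %.3f, %s; %d pos / %d neg)>\n",
              x$auc, x$raw_auc, x$orientation, x$n_pos, x$n_neg))
  invisible(x)
}

#' ROC-area report over the four window features
#'
#' @param windows usable window-feature data frame (see [usable_windows()]).
#' @param feature_cols feature columns to screen.
#' @return Data frame: feature, raw_auc, auc, orientation.
#' @export
roc_report <- function(windows,
                       feature_cols = c("rbp_theta", "rbp_alpha",
                                        "rbp_beta", "mp")) {
  rows <- lapply(feature_cols, function(f) {
    r <- roc_area(windows[[f]], windows$label)
    data.frame(feature = f, raw_auc = r$raw_auc, auc = r$auc,
               orientation = r$orientation)
  })
  do.call(rbind, rows)
}
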