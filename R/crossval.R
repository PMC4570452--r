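# Leave-one-subject-out cross-validation, grid search, metrics -------------

#' Build a confusion matrix from truth and prediction
#'
#' The positive class (+1) is slightly drowsy, the negative class (-1)
#' alert.
#'
#' @param truth,pred integer vectors in `{-1, +1}`.
#' @return A `confusion_matrix` list with counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(truth, pred) {
  structure(list(tp = sum(truth == 1 & pred == 1),
                 tn = sum(truth == -1 & pred == -1),
                 fp = sum(truth == -1 & pred == 1),
                 fn = sum(truth == 1 & pred == -1)),
            class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity in percent
#'
#' `Acc = (TP + TN) / (TP + TN + FP + FN)`, `Sens = TP / (TP + FN)`,
#' `Spec = TN / (TN + FP)`, each times 100. A zero denominator yields `NA`
#' for that component with a warning.
#'
#' @param cm a [confusion_matrix()] (any list with `tp`, `tn`, `fp`, `fn`).
#' @return Named numeric `c(acc, sens, spec)` in percent.
#' @export
svm_metrics <- function(cm) {
  tot <- cm$tp + cm$tn + cm$fp + cm$fn
  acc <- if (tot > 0) 100 * (cm$tp + cm$tn) / tot else NA_real_
  sens <- if (cm$tp + cm$fn > 0) 100 * cm$tp / (cm$tp + cm$fn) else NA_real_
  spec <- if (cm$tn + cm$fp > 0) 100 * cm$tn / (cm$tn + cm$fp) else NA_real_
  if (anyNA(c(acc, sens, spec)))
    warning("undefined metric: empty class in confusion matrix", call. = FALSE)
  c(acc = acc, sens = sens, spec = spec)
}

#' Reconstruct a confusion matrix from printed sensitivity/specificity
#'
#' Given published sensitivity and specificity (percent) together with the
#' class sizes, recovers the integer confusion counts by nearest-integer
#' inversion: `TP = round(sens * P / 100)`, `TN = round(spec * N / 100)`,
#' `FN = P - TP`, `FP = N - TN`. Warns if the re-derived rates differ from
#' the inputs by more than 0.005 percentage points, i.e. if no exact
#' integer pre-image exists at the printed precision.
#'
#' @param sens,spec percentages in `[0, 100]`.
#' @param P,N positive and negative class sizes (> 0).
#' @return A [confusion_matrix()].
#' @export
reconstruct_confusion <- function(sens, spec, P, N) {
  stopifnot(sens >= 0, sens <= 100, spec >= 0, spec <= 100, P > 0, N > 0)
  tp <- round(sens * P / 100)
  tn <- round(spec * N / 100)
  cm <- structure(list(tp = tp, tn = tn, fp = N - tn, fn = P - tp),
                  class = "confusion_matrix")
  if (abs(100 * tp / P - sens) > 0.005 || abs(100 * tn / N - spec) > 0.005)
    warning("reconstructed counts do not reproduce the printed rates to ",
            "0.005 pp", call. = FALSE)
  cm
}

#' Leave-one-subject-out cross-validation
#'
#' One round per subject: that subject's windows are held out, all other
#' subjects' windows train the model (feature scaling refitted per fold),
#' and the held-out windows are predicted. Pooled (count-weighted)
#' accuracy/sensitivity/specificity are computed over the union of all
#' held-out predictions; per-round accuracies are reported alongside.
#'
#' @param windows window-feature data frame with columns `subject`,
#'   `window_index`, `label` (-1/+1) and the feature columns; excluded
#'   windows must already be dropped (see [usable_windows()]).
#' @param feature_cols character vector of feature column names.
#' @param kernel,C,g,scale,tol,max_iter passed to [train_svm()].
#' @return A `ddd_cv`: per-round table, pooled [confusion_matrix()], pooled
#'   metrics, and the hyperparameters.
#' @export
loso_crossval <- function(windows, feature_cols, kernel = c("linear", "rbf"),
                          C = 1, g = 1, scale = TRUE, tol = 1e-3,
                          max_iter = 200000L) {
  kernel <- match.arg(kernel)
  if (anyNA(windows$label))
    stop("cross-validation contract error: unlabeled windows present; ",
         "drop them with usable_windows()", call. = FALSE)
  windows <- windows[order(windows$subject, windows$window_index), ,
                     drop = FALSE]
  subjects <- unique(windows$subject)
  if (length(subjects) < 2)
    stop("cross-validation contract error: need >= 2 subjects, got ",
         length(subjects), call. = FALSE)
  x <- as.matrix(windows[feature_cols])
  y <- as.integer(windows$label)
  truth <- integer(0); pred <- integer(0)
  rounds <- lapply(subjects, function(s) {
    te <- windows$subject == s
    ytr <- y[!te]
    if (length(unique(ytr)) < 2)
      stop("fold error: training fold for held-out subject ", s,
           " contains a single class", call. = FALSE)
    m <- train_svm(x[!te, , drop = FALSE], ytr, kernel, C, g, scale, tol,
                   max_iter)
    p <- predict(m, x[te, , drop = FALSE])
    truth <<- c(truth, y[te]); pred <<- c(pred, p)
    data.frame(subject = s, n = sum(te), correct = sum(p == y[te]),
               accuracy = 100 * mean(p == y[te]))
  })
  cm <- confusion_matrix(truth, pred)
  structure(list(rounds = do.call(rbind, rounds), cm = cm,
                 metrics = svm_metrics(cm), kernel = kernel, C = C,
                 g = if (kernel == "rbf") g else NA_real_,
                 n_windows = length(y)),
            class = "ddd_cv")
}

#' @export
print.ddd_cv <- function(x, ...) {
  cat(sprintf("<ddd_cv %s kernel, C = %g%s: Acc %.2f%%, Sens %.2f%%, Spec %.2f%% over %d windows / %d rounds>\n",
              x$kernel, x$C,
              if (!is.na(x$g)) sprintf(", g = %g", x$g) else "",
              x$metrics["acc"], x$metrics["sens"], x$metrics["spec"],
              x$n_windows, nrow(x$rounds)))
  invisible(x)
}

#' Exhaustive (C, g) grid optimisation of LOSO accuracy
#'
#' Runs [loso_crossval()] at every grid point and returns the point with
#' the highest pooled accuracy; ties are broken by the smallest `C`, then
#' the smallest `g`. The published procedure sweeps C and g from 0.01 to 10
#' in steps of 0.01 (10^6 RBF points); the default grids here are
#' logarithmic with 10 points per axis over the same range — pass
#' `published_grid()` to reproduce the full sweep (costly).
#'
#' @inheritParams loso_crossval
#' @param C_grid,g_grid numeric grids (non-empty); `g_grid` is ignored for
#'   the linear kernel.
#' @return A list: `best` (`ddd_cv`), `best_C`, `best_g`, and `grid` (a
#'   data frame of C, g, pooled accuracy).
#' @export
grid_optimize <- function(windows, feature_cols, kernel = c("linear", "rbf"),
                          C_grid = default_grid(), g_grid = default_grid(),
                          scale = TRUE, tol = 1e-3, max_iter = 200000L) {
  kernel <- match.arg(kernel)
  if (!length(C_grid) || (kernel == "rbf" && !length(g_grid)))
    stop("grid contract error: empty grid", call. = FALSE)
  if (kernel == "linear") g_grid <- 1
  pts <- expand.grid(C = sort(unique(C_grid)), g = sort(unique(g_grid)))
  pts <- pts[order(pts$C, pts$g), ]
  best <- NULL; best_acc <- -Inf
  acc <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cv <- loso_crossval(windows, feature_cols, kernel, pts$C[i], pts$g[i],
                        scale, tol, max_iter)
    acc[i] <- cv$metrics["acc"]
    if (acc[i] > best_acc) {        # strict: first (smallest C, g) wins ties
      best_acc <- acc[i]; best <- cv
    }
  }
  list(best = best, best_C = best$C, best_g = best$g,
       grid = data.frame(C = pts$C, g = pts$g, acc = acc))
}

#' Hyperparameter grids over the published 0.01-10 range
#'
#' `default_grid()` is logarithmic with `n` points; `published_grid()` is the
#' full arithmetic sweep in steps of 0.01 (1000 points per axis — expect
#' ~10^6 RBF grid points and a long run).
#'
#' @param n number of points for the logarithmic grid.
#' @return Numeric vector.
#' @export
default_grid <- function(n = 10) 10^seq(log10(0.01), log10(10), length.out = n)

#' @rdname default_grid
#' @export
published_grid <- function() seq(0.01, 10, by = 0.01)
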