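# Epoch features: FFT band power, relative band power, movement power ------

#' EEG band definition
#'
#' Half-open partition of the 4-30 Hz analysis range over 0.5 Hz FFT bins:
#' theta `[4, 8)`, alpha `[8, 13)`, beta `[13, 30]`. The conventional band
#' edges (theta up to 7 Hz, alpha from 8 Hz, alpha/beta meeting at 13 Hz)
#' leave a gap and a double-counted bin; a partition is required for the
#' relative-power denominator, so theta absorbs 7-8 Hz and 13 Hz goes to
#' beta.
#'
#' @param theta,alpha,beta numeric `c(lo, hi)` ranges in Hz; all are
#'   half-open `[lo, hi)` except beta, which is closed at the top.
#' @return A `band_definition` list.
#' @export
band_definition <- function(theta = c(4, 8), alpha = c(8, 13),
                            beta = c(13, 30)) {
  b <- structure(list(theta = theta, alpha = alpha, beta = beta),
                 class = "band_definition")
  edges <- c(theta, alpha, beta)
  if (any(diff(edges)[c(1, 3, 5)] <= 0) || theta[2] != alpha[1] ||
      alpha[2] != beta[1])
    stop("band definition error: bands must be increasing and contiguous",
         call. = FALSE)
  b
}

band_bin_index <- function(band, n, fs, include_upper = FALSE) {
  f <- (0:(n %/% 2)) * fs / n                 # one-sided bin frequencies
  sel <- f >= band[1] & (if (include_upper) f <= band[2] else f < band[2])
  which(sel)                                  # index into bins 0..n/2 (1-based)
}

#' FFT band power of one EEG epoch
#'
#' Sum of squared one-sided DFT magnitudes (rectangular window, no
#' scaling, no x2 energy correction) over the bins whose frequency lies in
#' `band`. For the default 256-sample epoch at 128 Hz the bin width is
#' 0.5 Hz.
#'
#' @param eeg_epoch numeric vector of one epoch's samples (length 256 by
#'   default contract).
#' @param band numeric `c(lo, hi)` in Hz.
#' @param fs sampling rate in Hz.
#' @param include_upper logical; include the upper edge bin (used for the
#'   top of the beta band).
#' @param n_expected expected epoch length (contract check; `NULL` skips).
#' @return Non-negative power (uV^2 * bins).
#' @export
band_power <- function(eeg_epoch, band, fs = 128, include_upper = FALSE,
                       n_expected = 256) {
  n <- length(eeg_epoch)
  if (!is.null(n_expected) && n != n_expected)
    stop("epoch contract error: expected ", n_expected, " samples, got ", n,
         call. = FALSE)
  if (band[1] < 0 || band[2] > fs / 2)
    stop("band outside [0, fs/2]", call. = FALSE)
  mag2 <- Mod(fft(eeg_epoch))[seq_len(n %/% 2 + 1)]^2
  sum(mag2[band_bin_index(band, n, fs, include_upper)])
}

three_band_power <- function(X, bands, fs) {
  # X: epoch_length x n_epochs matrix; returns 3 x n_epochs band powers
  n <- nrow(X)
  M2 <- Mod(mvfft(X))[seq_len(n %/% 2 + 1), , drop = FALSE]^2
  rbind(theta = colSums(M2[band_bin_index(bands$theta, n, fs), , drop = FALSE]),
        alpha = colSums(M2[band_bin_index(bands$alpha, n, fs), , drop = FALSE]),
        beta = colSums(M2[band_bin_index(bands$beta, n, fs, TRUE), , drop = FALSE]))
}

#' Relative band power of one EEG epoch
#'
#' Each band's FFT power divided by the summed power of the three bands,
#' in percent; the three components sum to 100 by construction.
#'
#' @inheritParams band_power
#' @param bands a [band_definition()].
#' @return Named numeric `c(rbp_theta, rbp_alpha, rbp_beta)` in percent.
#' @export
relative_band_power <- function(eeg_epoch, bands = band_definition(),
                                fs = 128, n_expected = 256) {
  p <- c(band_power(eeg_epoch, bands$theta, fs, FALSE, n_expected),
         band_power(eeg_epoch, bands$alpha, fs, FALSE, n_expected),
         band_power(eeg_epoch, bands$beta, fs, TRUE, n_expected))
  if (sum(p) <= 0)
    stop("degenerate epoch: total three-band power is zero", call. = FALSE)
  stats::setNames(100 * p / sum(p), c("rbp_theta", "rbp_alpha", "rbp_beta"))
}

#' Movement power of one gyroscope epoch
#'
#' Population standard deviation (divide by N) of the per-sample mean of
#' the three gyroscope axes within the epoch; quantifies head-movement
#' intensity in device units.
#'
#' @param gyro_x,gyro_y,gyro_z equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
movement_power <- function(gyro_x, gyro_y, gyro_z) {
  if (length(gyro_y) != length(gyro_x) || length(gyro_z) != length(gyro_x))
    stop("epoch contract error: gyro axes differ in length", call. = FALSE)
  avg <- (gyro_x + gyro_y + gyro_z) / 3
  sqrt(mean((avg - mean(avg))^2))
}

#' Per-epoch feature extraction for a whole session
#'
#' Computes the four features (relative band powers and movement power) for
#' every epoch of an [segment_epochs()] result. Epochs whose three-band EEG
#' power is zero are flagged degenerate (features `NA`) instead of erroring.
#'
#' @param epochs an `epoch_set`.
#' @param bands a [band_definition()].
#' @return Data frame with columns `epoch`, `rbp_theta`, `rbp_alpha`,
#'   `rbp_beta`, `mp`, `degenerate`.
#' @export
epoch_features <- function(epochs, bands = band_definition()) {
  fs <- epochs$sample_rate
  if (epochs$n_epochs == 0)
    return(data.frame(epoch = integer(), rbp_theta = numeric(),
                      rbp_alpha = numeric(), rbp_beta = numeric(),
                      mp = numeric(), degenerate = logical()))
  P <- three_band_power(epochs$eeg, bands, fs)
  tot <- colSums(P)
  degenerate <- tot <= 0
  tot[degenerate] <- NA_real_
  avg <- (epochs$gyro_x + epochs$gyro_y + epochs$gyro_z) / 3
  mp <- sqrt(colMeans(avg^2) - colMeans(avg)^2)
  mp[mp < 0 | is.nan(mp)] <- 0                 # guard tiny negative rounding
  data.frame(epoch = seq_len(epochs$n_epochs),
             rbp_theta = 100 * P["theta", ] / tot,
             rbp_alpha = 100 * P["alpha", ] / tot,
             rbp_beta = 100 * P["beta", ] / tot,
             mp = mp, degenerate = degenerate)
}

#' Average epoch features into 1-min windows aligned with ground truth
#'
#' Component-wise arithmetic mean over consecutive disjoint blocks of
#' `epochs_per_window` epoch feature sets (default 30, i.e. one minute of
#' 2-s epochs), synchronising the features with the per-minute video-based
#' labels: window i receives `minute_labels[i]`. Degenerate or explicitly
#' dropped epochs are excluded from their window's mean; a window with more
#' than half its epochs excluded, or with a mid/late (`NA`) label, is
#' emitted but flagged `excluded`.
#'
#' @param feats epoch-feature data frame from [epoch_features()].
#' @param minute_labels integer labels in `{-1, +1, NA}`, one per window.
#' @param subject_id subject identifier for the output rows.
#' @param epochs_per_window epochs averaged per window (default 30).
#' @param drop_epochs integer indices of epochs to exclude from the means
#'   (e.g. filter start-up transients).
#' @return Data frame with columns `subject`, `window_index`, `rbp_theta`,
#'   `rbp_alpha`, `rbp_beta`, `mp`, `label`, `excluded`.
#' @export
average_windows <- function(feats, minute_labels, subject_id = "S1",
                            epochs_per_window = 30, drop_epochs = integer()) {
  n_ep <- nrow(feats)
  if (n_ep < epochs_per_window)
    stop("alignment error: ", n_ep, " epoch features < one window (",
         epochs_per_window, ")", call. = FALSE)
  n_win <- n_ep %/% epochs_per_window
  if (length(minute_labels) < n_win)
    stop("alignment error: ", length(minute_labels), " labels for ", n_win,
         " windows", call. = FALSE)
  use <- !feats$degenerate
  use[drop_epochs[drop_epochs <= n_ep]] <- FALSE
  cols <- c("rbp_theta", "rbp_alpha", "rbp_beta", "mp")
  out <- lapply(seq_len(n_win), function(i) {
    idx <- ((i - 1) * epochs_per_window + 1):(i * epochs_per_window)
    ok <- idx[use[idx]]
    v <- if (length(ok)) colMeans(feats[ok, cols, drop = FALSE])
         else stats::setNames(rep(NA_real_, 4), cols)
    flagged <- length(ok) < epochs_per_window / 2
    c(as.list(v), list(n_used = length(ok), flagged = flagged))
  })
  lab <- as.integer(minute_labels[seq_len(n_win)])
  flagged <- vapply(out, `[[`, logical(1), "flagged")
  data.frame(subject = subject_id, window_index = seq_len(n_win),
             rbp_theta = vapply(out, `[[`, numeric(1), "rbp_theta"),
             rbp_alpha = vapply(out, `[[`, numeric(1), "rbp_alpha"),
             rbp_beta = vapply(out, `[[`, numeric(1), "rbp_beta"),
             mp = vapply(out, `[[`, numeric(1), "mp"),
             label = lab,
             excluded = is.na(lab) | flagged,
             row.names = NULL)
}

#' Keep only windows usable for binary classification
#'
#' Drops windows flagged excluded (mid/late-stage label or too many
#' degenerate epochs).
#'
#' @param windows window-feature data frame.
#' @return Filtered data frame.
#' @export
usable_windows <- function(windows) {
  windows[!windows$excluded & !is.na(windows$label), , drop = FALSE]
}
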