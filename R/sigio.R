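# Session data model and CSV I/O -------------------------------------------

LABEL_TOKENS <- c(alert = -1L, slight = 1L, mid_late = NA_integer_)

#' Construct a raw recording session
#'
#' A session bundles the four synchronous signal channels of the headset —
#' one bipolar EEG channel in microvolts plus the three gyroscope axes in
#' device units — with the per-minute video-based ground-truth labels.
#'
#' Label coding follows the classifier convention: alert = -1 (negative
#' class), slightly drowsy = +1 (positive class); mid/late-stage drowsy
#' minutes are retained as `NA` and excluded from binary analysis.
#'
#' @param subject_id character scalar identifying the subject.
#' @param eeg numeric vector, EEG samples in microvolts.
#' @param gyro_x,gyro_y,gyro_z numeric vectors, angular-rate samples in
#'   device units (X: yaw/nod e.g. yawning, Y: shaking, Z: swaying).
#' @param minute_labels integer vector over 1-min windows with values in
#'   `{-1, +1, NA}`, or a character vector of tokens
#'   `{"alert", "slight", "mid_late"}`.
#' @param sample_rate sampling rate in Hz (default 128).
#' @return An object of class `raw_session`.
#' @export
raw_session <- function(subject_id, eeg, gyro_x, gyro_y, gyro_z,
                        minute_labels, sample_rate = 128) {
  if (is.character(minute_labels)) minute_labels <- map_labels(minute_labels)
  s <- structure(
    list(subject_id = as.character(subject_id)[1],
         sample_rate = sample_rate,
         eeg = as.numeric(eeg),
         gyro_x = as.numeric(gyro_x), gyro_y = as.numeric(gyro_y),
         gyro_z = as.numeric(gyro_z),
         minute_labels = as.integer(minute_labels)),
    class = "raw_session")
  validate_session(s)
}

validate_session <- function(s) {
  n <- length(s$eeg)
  lens <- c(length(s$gyro_x), length(s$gyro_y), length(s$gyro_z))
  if (any(lens != n))
    stop("session format error: channel lengths differ (eeg ", n,
         ", gyro ", paste(lens, collapse = "/"), ")", call. = FALSE)
  if (n %% s$sample_rate != 0)
    stop("session format error: length ", n,
         " is not a multiple of the sample rate ", s$sample_rate,
         call. = FALSE)
  n_min <- floor(n / s$sample_rate / 60)
  if (length(s$minute_labels) != n_min)
    stop("session format error: ", length(s$minute_labels),
         " minute labels for ", n_min, " minutes of signal", call. = FALSE)
  bad <- !is.na(s$minute_labels) & !(s$minute_labels %in% c(-1L, 1L))
  if (any(bad))
    stop("session format error: labels must be -1, +1 or NA", call. = FALSE)
  s
}

map_labels <- function(tokens) {
  tokens <- trimws(tokens)
  unknown <- setdiff(unique(tokens), names(LABEL_TOKENS))
  if (length(unknown))
    stop("label format error: unknown label token(s) ",
         paste(sQuote(unknown), collapse = ", "),
         " (expected alert/slight/mid_late)", call. = FALSE)
  unname(LABEL_TOKENS[tokens])
}

unmap_labels <- function(codes) {
  out <- rep("mid_late", length(codes))
  out[!is.na(codes) & codes == -1L] <- "alert"
  out[!is.na(codes) & codes == 1L] <- "slight"
  out
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session %s: %.1f min @ %g Hz, %d minute labels (%d alert / %d slight / %d mid_late)>\n",
              x$subject_id, length(x$eeg) / x$sample_rate / 60, x$sample_rate,
              length(x$minute_labels),
              sum(x$minute_labels == -1L, na.rm = TRUE),
              sum(x$minute_labels == 1L, na.rm = TRUE),
              sum(is.na(x$minute_labels))))
  invisible(x)
}

#' Read a session from its sample CSV and companion label CSV
#'
#' The sample CSV must have header `time_s,eeg_uv,gyro_x,gyro_y,gyro_z`,
#' one row per sample at the stated rate. The `time_s` column is advisory:
#' sample index / rate is authoritative. The label CSV has header
#' `minute_index,label` with labels in `{alert, slight, mid_late}`; rows are
#' sorted by `minute_index` (1-based).
#'
#' @param path path of the sample CSV.
#' @param labels_path path of the label CSV; default replaces a trailing
#'   `_session.csv` with `_labels.csv`.
#' @param subject_id subject identifier; default derived from the file name.
#' @param sample_rate sampling rate in Hz.
#' @return A [raw_session()].
#' @export
read_session <- function(path, labels_path = NULL, subject_id = NULL,
                         sample_rate = 128) {
  if (is.null(labels_path))
    labels_path <- sub("_session\\.csv$", "_labels.csv", path)
  if (is.null(subject_id))
    subject_id <- sub("_session\\.csv$", "", basename(path))
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "eeg_uv", "gyro_x", "gyro_y", "gyro_z")
  if (!all(need %in% names(d)))
    stop("session format error: expected columns ",
         paste(need, collapse = ","), call. = FALSE)
  lab <- read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("minute_index", "label") %in% names(lab)))
    stop("label format error: expected columns minute_index,label",
         call. = FALSE)
  lab <- lab[order(lab$minute_index), ]
  raw_session(subject_id, d$eeg_uv, d$gyro_x, d$gyro_y, d$gyro_z,
              map_labels(lab$label), sample_rate)
}

#' Write a session to its sample CSV and companion label CSV
#'
#' @param session a [raw_session()].
#' @param path,labels_path output CSV paths (same layout as [read_session()]).
#' @return Invisibly, `path`.
#' @export
write_session <- function(session, path,
                          labels_path = sub("_session\\.csv$", "_labels.csv", path)) {
  n <- length(session$eeg)
  d <- data.frame(time_s = (seq_len(n) - 1) / session$sample_rate,
                  eeg_uv = session$eeg,
                  gyro_x = session$gyro_x, gyro_y = session$gyro_y,
                  gyro_z = session$gyro_z)
  write.csv(d, path, row.names = FALSE)
  lab <- data.frame(minute_index = seq_along(session$minute_labels),
                    label = unmap_labels(session$minute_labels))
  write.csv(lab, labels_path, row.names = FALSE)
  invisible(path)
}

# Epoch segmentation --------------------------------------------------------

#' Segment a session into contiguous 2-s epochs
#'
#' Cuts every channel into contiguous, non-overlapping epochs of
#' `2 * sample_rate` samples aligned to sample 1; a trailing remainder
#' shorter than one epoch is dropped (a message reports how many samples).
#'
#' @param session a [raw_session()].
#' @param epoch_s epoch duration in seconds (default 2).
#' @return An `epoch_set`: a list with per-channel `epoch_length x n_epochs`
#'   matrices `eeg`, `gyro_x`, `gyro_y`, `gyro_z`, plus `n_epochs`,
#'   `sample_rate` and `subject_id`. Zero epochs (empty matrices) if the
#'   session is shorter than one epoch.
#' @export
segment_epochs <- function(session, epoch_s = 2) {
  len <- as.integer(session$sample_rate * epoch_s)
  n <- length(session$eeg)
  n_ep <- as.integer(n %/% len)
  if (n %% len > 0)
    message("segment_epochs: dropping trailing ", n %% len, " samples (< 1 epoch)")
  keep <- seq_len(n_ep * len)
  as_mat <- function(x) matrix(x[keep], nrow = len, ncol = n_ep)
  structure(list(eeg = as_mat(session$eeg),
                 gyro_x = as_mat(session$gyro_x),
                 gyro_y = as_mat(session$gyro_y),
                 gyro_z = as_mat(session$gyro_z),
                 n_epochs = n_ep, epoch_length = len,
                 sample_rate = session$sample_rate,
                 subject_id = session$subject_id),
            class = "epoch_set")
}

# Feature CSV ----------------------------------------------------------------

#' Write / read the per-window feature table
#'
#' Columns: `subject,window_index,rbp_theta,rbp_alpha,rbp_beta,mp,label`,
#' with `label` written as `-1`, `1` or `excluded`.
#'
#' @param features window-feature data frame from [average_windows()].
#' @param path CSV path.
#' @return `write_features` invisibly returns `path`; `read_features`
#'   returns the data frame with an integer `label` column (`NA` = excluded).
#' @export
write_features <- function(features, path) {
  out <- features[c("subject", "window_index", "rbp_theta", "rbp_alpha",
                    "rbp_beta", "mp", "label")]
  drop <- is.na(features$label) |
    (if (is.null(features$excluded)) FALSE else features$excluded)
  out$label <- ifelse(drop, "excluded", as.character(features$label))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lab <- rep(NA_integer_, nrow(d))
  lab[d$label == "-1"] <- -1L
  lab[d$label == "1"] <- 1L
  bad <- !(d$label %in% c("-1", "1", "excluded"))
  if (any(bad))
    stop("feature format error: unknown label token(s) ",
         paste(sQuote(unique(d$label[bad])), collapse = ", "), call. = FALSE)
  d$label <- lab
  d$excluded <- is.na(lab)
  d
}
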