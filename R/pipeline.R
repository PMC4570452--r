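# End-to-end pipeline orchestration ----------------------------------------

#' Pipeline configuration
#'
#' Collects every stage's parameters into one validated object. Either
#' simulated input (`simulate = TRUE`, governed by `profile`) or a
#' directory of `<subject>_session.csv` / `<subject>_labels.csv` files.
#'
#' @param simulate generate a synthetic cohort (default `TRUE`).
#' @param profile [sim_profile()] for simulation.
#' @param input_dir directory of session CSVs when `simulate = FALSE`.
#' @param filter a [filter_spec()].
#' @param bands a [band_definition()].
#' @param epochs_per_window epochs averaged per window (default 30).
#' @param drop_transient_epochs initial epochs per session dropped from
#'   window means while the causal filters settle (default 2).
#' @param kernels kernels to evaluate.
#' @param C_grid,g_grid hyperparameter grids (see [default_grid()]).
#' @param feature_sets named list of feature-column sets; the default
#'   compares EEG-only, movement-power-only and hybrid.
#' @param scale standardise features inside each SVM fit.
#' @param seed master seed for simulation.
#' @param out_dir if non-`NULL`, reports and feature CSVs are written here.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, profile = sim_profile(),
                            input_dir = NULL, filter = filter_spec(),
                            bands = band_definition(),
                            epochs_per_window = 30,
                            drop_transient_epochs = 2,
                            kernels = c("linear", "rbf"),
                            C_grid = default_grid(),
                            g_grid = default_grid(),
                            feature_sets = list(
                              eeg = c("rbp_theta", "rbp_alpha", "rbp_beta"),
                              mp = "mp",
                              hybrid = c("rbp_theta", "rbp_alpha",
                                         "rbp_beta", "mp")),
                            scale = TRUE, seed = 1, out_dir = NULL) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  if (!simulate && is.null(input_dir))
    stop("config error [input]: need input_dir when simulate = FALSE",
         call. = FALSE)
  if (!all(kernels %in% c("linear", "rbf")))
    stop("config error [classify]: kernels must be linear/rbf", call. = FALSE)
  if (epochs_per_window < 1 || !length(C_grid) || !length(g_grid))
    stop("config error [classify]: empty grid or window size < 1",
         call. = FALSE)
  cfg
}

#' Extract window features for a list of sessions
#'
#' Per session: optional 60 Hz notch, causal band-pass, 2-s epoch
#' segmentation, per-epoch features, 1-min window averaging against the
#' session's minute labels. Stage counts (epochs, degenerate epochs,
#' windows, excluded windows) are reported via `message()`.
#'
#' @param sessions list of [raw_session()] objects.
#' @param filter a [filter_spec()].
#' @param bands a [band_definition()].
#' @param epochs_per_window epochs per window.
#' @param drop_transient_epochs initial epochs excluded from window means.
#' @param quiet suppress stage-count messages.
#' @return Combined window-feature data frame.
#' @export
extract_cohort_features <- function(sessions, filter = filter_spec(),
                                    bands = band_definition(),
                                    epochs_per_window = 30,
                                    drop_transient_epochs = 2,
                                    quiet = FALSE) {
  per <- lapply(sessions, function(s) {
    f <- preprocess_session(s, filter)
    ep <- segment_epochs(f)
    feats <- epoch_features(ep, bands)
    w <- average_windows(feats, s$minute_labels, s$subject_id,
                         epochs_per_window,
                         drop_epochs = seq_len(drop_transient_epochs))
    if (!quiet)
      message(sprintf(
        "[features] %s: %d epochs (%d degenerate), %d windows (%d excluded)",
        s$subject_id, nrow(feats), sum(feats$degenerate), nrow(w),
        sum(w$excluded)))
    w
  })
  do.call(rbind, per)
}

#' Run the full detection pipeline
#'
#' (Simulate or read) sessions, filter, epoch, extract features, average
#' windows, screen single-feature ROC areas, and run LOSO grid-optimised
#' cross-validation for each configured feature set and kernel. The
#' returned report embeds the resolved configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return A `ddd_pipeline` list: `features` (all windows), `roc`,
#'   `cv` (one row per feature set x kernel with best C/g and pooled
#'   metrics), `cv_detail` (the `ddd_cv` objects), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  sessions <- if (config$simulate) {
    simulate_cohort(config$profile, config$seed, filter = config$filter)
  } else {
    paths <- sort(list.files(config$input_dir, "_session\\.csv$",
                             full.names = TRUE))
    if (!length(paths))
      stop("pipeline error [sigio]: no *_session.csv files in ",
           config$input_dir, call. = FALSE)
    lapply(paths, read_session)
  }
  features <- extract_cohort_features(sessions, config$filter, config$bands,
                                      config$epochs_per_window,
                                      config$drop_transient_epochs)
  usable <- usable_windows(features)
  message(sprintf("[windows] %d total, %d usable (%d alert / %d drowsy)",
                  nrow(features), nrow(usable), sum(usable$label == -1),
                  sum(usable$label == 1)))
  roc <- roc_report(usable)

  cv_detail <- list()
  cv_rows <- list()
  for (fs_name in names(config$feature_sets)) {
    for (k in config$kernels) {
      opt <- grid_optimize(usable, config$feature_sets[[fs_name]], k,
                           config$C_grid, config$g_grid, config$scale)
      key <- paste(fs_name, k, sep = ".")
      cv_detail[[key]] <- opt$best
      m <- opt$best$metrics
      cv_rows[[key]] <- data.frame(
        feature_set = fs_name, kernel = k, C = opt$best_C, g = opt$best_g,
        acc = m[["acc"]], sens = m[["sens"]], spec = m[["spec"]])
      message(sprintf(
        "[crossval] %-6s %-6s best C = %-8.4g g = %-8.4g Acc %.2f%% Sens %.2f%% Spec %.2f%%",
        fs_name, k, opt$best_C,
        if (is.na(opt$best_g)) NA else opt$best_g, m[["acc"]], m[["sens"]],
        m[["spec"]]))
    }
  }
  cv <- do.call(rbind, c(cv_rows, list(make.row.names = FALSE)))

  res <- structure(list(features = features, roc = roc, cv = cv,
                        cv_detail = cv_detail,
                        config = config, seed = config$seed),
                   class = "ddd_pipeline")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_features(features, file.path(config$out_dir, "features.csv"))
    write.csv(roc, file.path(config$out_dir, "roc_report.csv"),
              row.names = FALSE)
    write.csv(cv, file.path(config$out_dir, "cv_report.csv"),
              row.names = FALSE)
    cfg <- config
    cfg$profile <- unclass(cfg$profile)
    cfg$filter <- unclass(cfg$filter)
    cfg$bands <- unclass(cfg$bands)
    jsonlite::write_json(unclass(cfg), file.path(config$out_dir,
                                                 "config_resolved.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  res
}

#' @export
print.ddd_pipeline <- function(x, ...) {
  cat("Drowsiness-detection pipeline report\n")
  cat(sprintf("  seed %s; %d windows (%d usable)\n", format(x$seed),
              nrow(x$features), nrow(usable_windows(x$features))))
  cat("  ROC areas:\n")
  print(x$roc, row.names = FALSE)
  cat("  LOSO cross-validation (best grid point per feature set x kernel):\n")
  print(x$cv, row.names = FALSE, digits = 4)
  invisible(x)
}
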