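# Shared fixtures and independent oracles for the test suite.

FS <- 128
EPOCH_N <- 256

# pure sinusoid epoch (amplitude A, frequency f Hz)
sin_epoch <- function(f, A = 1, n = EPOCH_N, fs = FS, phase = 0) {
  A * sin(2 * pi * f * (0:(n - 1)) / fs + phase)
}

# Brute-force DFT band-power oracle: explicit complex-exponential sums,
# independent of stats::fft. Matches the half-open band convention.
dft_band_power <- function(x, band, fs = FS, include_upper = FALSE) {
  n <- length(x)
  ks <- 0:(n %/% 2)
  f <- ks * fs / n
  sel <- f >= band[1] & (if (include_upper) f <= band[2] else f < band[2])
  total <- 0
  for (k in ks[sel]) {
    e <- exp(-2i * pi * k * (0:(n - 1)) / n)
    total <- total + Mod(sum(x * e))^2
  }
  total
}

# Pairwise Mann-Whitney AUC oracle: count concordant pairs, ties = 1/2.
auc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# small deterministic session: `minutes` minutes of structured signal
tiny_session <- function(minutes = 2, subject = "T1", labels = NULL) {
  n <- minutes * 60 * FS
  t <- (0:(n - 1)) / FS
  if (is.null(labels)) labels <- rep(c(-1L, 1L), length.out = minutes)
  raw_session(subject,
              eeg = 10 * sin(2 * pi * 10 * t) + 4 * sin(2 * pi * 6 * t),
              gyro_x = sin(2 * pi * 0.5 * t), gyro_y = rep(0.25, n),
              gyro_z = cos(2 * pi * 0.25 * t),
              minute_labels = labels)
}

# small separable window table for classifier tests: MP separates classes
separable_windows <- function(n_subjects = 4, per_subject = 10, seed = 99) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    lab <- rep(c(-1L, 1L), length.out = per_subject)
    data.frame(subject = sprintf("S%d", s),
               window_index = seq_len(per_subject),
               rbp_theta = rnorm(per_subject, 17, 2),
               rbp_alpha = rnorm(per_subject, 40, 2),
               rbp_beta = rnorm(per_subject, 43, 2),
               mp = ifelse(lab == 1, 170, 75) + rnorm(per_subject, 0, 5),
               label = lab, excluded = FALSE)
  }))
}

# memoised expensive fixtures (default synthetic cohort at seed 1)
.fixtures <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixtures$sessions))
    .fixtures$sessions <- simulate_cohort(sim_profile(), seed = 1)
  .fixtures$sessions
}

default_cohort_features <- function() {
  if (is.null(.fixtures$features))
    .fixtures$features <- extract_cohort_features(default_cohort(),
                                                  quiet = TRUE)
  .fixtures$features
}
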