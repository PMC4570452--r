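# Causal digital filtering of the EEG channel ------------------------------
#
# The headset's analog front end is a 2nd-order Butterworth high-pass at
# 4 Hz followed by a 4th-order Butterworth low-pass at 30 Hz; the on-chip
# digital band-pass mirrors that chain. Filtering is causal (forward-only,
# zero initial state), as a streaming device would run it. The 60 Hz notch
# is only meaningful indoors and is therefore off by default.

#' Band-pass / notch filter specification
#'
#' @param low_cut high-pass corner in Hz (default 4).
#' @param high_cut low-pass corner in Hz (default 30).
#' @param hp_order,lp_order Butterworth orders (defaults 2 and 4, matching
#'   the analog chain).
#' @param notch_freq power-line frequency in Hz (default 60).
#' @param notch_q notch quality factor (default 30).
#' @param notch_enabled logical; default `FALSE` (no mains in a car).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_cut = 4, high_cut = 30, hp_order = 2,
                        lp_order = 4, notch_freq = 60, notch_q = 30,
                        notch_enabled = FALSE) {
  spec <- structure(list(low_cut = low_cut, high_cut = high_cut,
                         hp_order = as.integer(hp_order),
                         lp_order = as.integer(lp_order),
                         notch_freq = notch_freq, notch_q = notch_q,
                         notch_enabled = isTRUE(notch_enabled)),
                    class = "filter_spec")
  if (!(low_cut > 0 && low_cut < high_cut))
    stop("filter configuration error: need 0 < low_cut < high_cut", call. = FALSE)
  if (spec$hp_order < 1 || spec$lp_order < 1)
    stop("filter configuration error: orders must be >= 1", call. = FALSE)
  if (notch_q <= 0)
    stop("filter configuration error: notch_q must be > 0", call. = FALSE)
  spec
}

check_spec_fs <- function(spec, fs) {
  if (spec$high_cut >= fs / 2)
    stop("filter configuration error: high_cut ", spec$high_cut,
         " Hz >= Nyquist (", fs / 2, " Hz)", call. = FALSE)
  if (spec$notch_enabled && spec$notch_freq >= fs / 2)
    stop("filter configuration error: notch_freq >= Nyquist", call. = FALSE)
  invisible(spec)
}

# Butterworth design via the bilinear transform, returned as second-order
# sections (rows b0 b1 b2 a0 a1 a2). Handles any order; odd orders get one
# first-order section (third coefficients zero).
butter_sos <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stop("cutoff outside (0, fs/2)", call. = FALSE)
  wc <- 2 * fs * tan(pi * fc / fs)             # prewarped analog corner, rad/s
  k <- seq_len(n)
  p <- wc * exp(1i * pi * (0.5 + (2 * k - 1) / (2 * n)))  # LP prototype poles
  if (type == "high") p <- wc^2 / p                       # LP -> HP transform
  z_pole <- (1 + p / (2 * fs)) / (1 - p / (2 * fs))       # bilinear
  z_zero <- if (type == "low") -1 else 1                  # digital zeros
  z_ref <- if (type == "low") 1 else -1                   # unity-gain point
  # pair conjugate poles into biquads (poles come in conjugate pairs except
  # one real pole for odd n, which sits at angle pi i.e. real axis)
  ord <- order(abs(Im(z_pole)), decreasing = TRUE)
  z_pole <- z_pole[ord]
  sos <- NULL
  i <- 1
  while (i <= n) {
    if (abs(Im(z_pole[i])) > 1e-12) {
      pp <- z_pole[i]                                   # with its conjugate
      a <- c(1, -2 * Re(pp), Mod(pp)^2)
      b <- c(1, -2 * z_zero, 1)
      i <- i + 2
    } else {
      pp <- Re(z_pole[i])
      a <- c(1, -pp, 0)
      b <- c(1, -z_zero, 0)
      i <- i + 1
    }
    g <- sum(b * z_ref^-(0:2)) / sum(a * z_ref^-(0:2))  # real at z_ref
    sos <- rbind(sos, c(b / g, a))
  }
  unname(sos)
}

# RBJ audio-cookbook notch biquad.
notch_sos <- function(f0, Q, fs) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  a0 <- 1 + al
  matrix(c(1 / a0, -2 * cos(w0) / a0, 1 / a0,
           1, -2 * cos(w0) / a0, (1 - al) / a0), nrow = 1)
}

bandpass_sos <- function(spec, fs) {
  check_spec_fs(spec, fs)
  rbind(butter_sos(spec$hp_order, spec$low_cut, fs, "high"),
        butter_sos(spec$lp_order, spec$high_cut, fs, "low"))
}

#' Causal 4-30 Hz band-pass filtering of an EEG series
#'
#' Cascade of a `hp_order` Butterworth high-pass at `low_cut` and an
#' `lp_order` Butterworth low-pass at `high_cut` (bilinear-transform
#' design), run causally from zero initial state.
#'
#' @param x numeric signal (microvolts).
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, spec = filter_spec(), fs = 128) {
  sosfilt_cpp(bandpass_sos(spec, fs), as.numeric(x))
}

#' Causal 60 Hz notch filtering
#'
#' Second-order constrained notch (quality factor `spec$notch_q`); requires
#' `spec$notch_enabled`.
#'
#' @inheritParams bandpass
#' @return Filtered signal, same length as `x`.
#' @export
notch60 <- function(x, spec = filter_spec(notch_enabled = TRUE), fs = 128) {
  if (!spec$notch_enabled)
    stop("filter configuration error: notch filter is not enabled", call. = FALSE)
  check_spec_fs(spec, fs)
  sosfilt_cpp(notch_sos(spec$notch_freq, spec$notch_q, fs), as.numeric(x))
}

#' Analytic frequency response of the designed filters
#'
#' Evaluates the designed transfer function H(e^{i 2 pi f / fs}) directly
#' from the second-order-section coefficients — independent of the
#' time-domain filtering routine.
#'
#' @param spec a [filter_spec()].
#' @param f numeric vector of probe frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param which `"bandpass"` or `"notch"`.
#' @return Complex response at each frequency.
#' @export
filter_response <- function(spec, f, fs = 128,
                            which = c("bandpass", "notch")) {
  which <- match.arg(which)
  sos <- if (which == "bandpass") bandpass_sos(spec, fs)
         else notch_sos(spec$notch_freq, spec$notch_q, fs)
  sos_response(sos, f, fs)
}

sos_response <- function(sos, f, fs) {
  zinv <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (r in seq_len(nrow(sos))) {
    num <- sos[r, 1] + sos[r, 2] * zinv + sos[r, 3] * zinv^2
    den <- 1 + sos[r, 5] * zinv + sos[r, 6] * zinv^2
    h <- h * num / den
  }
  h
}

#' Apply the configured preprocessing chain to a session's EEG channel
#'
#' Runs the notch first (if enabled) and then the band-pass, on the EEG
#' channel only; the gyroscope is already conditioned inside the sensor and
#' passes through untouched.
#'
#' @param session a [raw_session()].
#' @param spec a [filter_spec()].
#' @return The session with a filtered `eeg` channel.
#' @export
preprocess_session <- function(session, spec = filter_spec()) {
  fs <- session$sample_rate
  x <- session$eeg
  if (spec$notch_enabled) x <- notch60(x, spec, fs)
  session$eeg <- bandpass(x, spec, fs)
  session
}
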