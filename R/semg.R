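#' Band-pass and notch filter a surface-EMG trace
#'
#' Applies the sEMG conditioning used for muscle-state monitoring: a 45-500 Hz
#' band-pass (4th-order Butterworth) followed by a 50 Hz mains notch
#' (2nd-order IIR, Q = 30), both run forward-backward for zero phase.
#'
#' @param data Tibble with columns `t_s` and `uv` (microvolts), or a numeric
#'   vector of samples.
#' @param fs_hz Sampling rate; must exceed 1000 Hz so the 500 Hz band edge is
#'   realizable.
#' @param band_hz Band-pass corner frequencies.
#' @param notch_hz Mains frequency to reject.
#' @param notch_q Notch quality factor.
#' @return Input with `uv` replaced by the filtered samples (vector in,
#'   vector out).
#' @export
filter_semg <- function(data, fs_hz = 1024, band_hz = c(45, 500),
                        notch_hz = 50, notch_q = 30) {
  assert_that(fs_hz > 1000, "sampling rate must exceed 1000 Hz (500 Hz band edge)")
  x <- if (is.data.frame(data)) data$uv else as.numeric(data)
  assert_that(all(is.finite(x)), "non-finite sEMG samples")
  nyq <- fs_hz / 2
  bp <- signal::butter(4, band_hz / nyq, type = "pass")
  y <- signal::filtfilt(bp, x)
  # biquad notch: poles pulled toward the unit-circle zeros at +-w0
  w0 <- 2 * pi * notch_hz / fs_hz
  bw <- w0 / notch_q
  r <- 1 - bw / 2
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  gain <- sum(b) / sum(a)  # unit DC gain
  y <- signal::filtfilt(signal::Arma(b = b / gain, a = a), y)
  if (is.data.frame(data)) {
    data$uv <- y
    data
  } else {
    y
  }
}

#' Sliding RMS envelope of an sEMG trace
#'
#' Root mean square over a sliding window of `window` samples (195.3 ms at
#' 1024 Hz for the default window of 200), the quantization used for the
#' muscle-activity amplitudes.
#'
#' @inheritParams filter_semg
#' @param window Window length in samples.
#' @return Tibble with columns `t_s` (window-center time, when available)
#'   and `rms_uv`.
#' @export
rms_envelope <- function(data, window = 200L, fs_hz = 1024) {
  x <- if (is.data.frame(data)) data$uv else as.numeric(data)
  n <- length(x)
  assert_that(n >= window, "trace shorter than the RMS window")
  # exact sliding mean of x^2 via cumulative sums
  cs <- cumsum(c(0, x^2))
  ms <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  rms <- sqrt(pmax(ms, 0))
  t_mid <- if (is.data.frame(data) && "t_s" %in% names(data)) {
    (data$t_s[seq_len(n - window + 1L)] + data$t_s[window:n]) / 2
  } else {
    (seq_len(n - window + 1L) + window / 2 - 1) / fs_hz
  }
  tibble::tibble(t_s = t_mid, rms_uv = rms)
}

#' Normalize an sEMG envelope to maximum voluntary contraction
#'
#' Expresses mean envelope amplitude during a measurement as percent of the
#' participant's MVC reference recorded in the matching body position. The
#' MVC reference statistic is the mean of the top `peak_s` seconds of the
#' MVC envelope (a robust peak), and the resting baseline is reported
#' alongside.
#'
#' @param envelope Envelope tibble (from [rms_envelope()]) or numeric vector
#'   for the measurement of interest.
#' @param mvc_envelope Envelope of the MVC recording (same position).
#' @param baseline_envelope Optional envelope of the resting baseline.
#' @param fs_hz Envelope sampling rate used to size the peak window.
#' @param peak_s Length of the MVC peak statistic window in seconds.
#' @return A one-row tibble: `activity_pct`, `mvc_reference_uv`,
#'   `baseline_uv`.
#' @export
normalize_mvc <- function(envelope, mvc_envelope, baseline_envelope = NULL,
                          fs_hz = 1024, peak_s = 0.5) {
  get_vals <- function(e) if (is.data.frame(e)) e$rms_uv else as.numeric(e)
  env <- get_vals(envelope)
  mvc <- get_vals(mvc_envelope)
  k <- max(1L, min(length(mvc), round(peak_s * fs_hz)))
  mvc_ref <- mean(sort(mvc, decreasing = TRUE)[seq_len(k)])
  base <- if (!is.null(baseline_envelope)) mean(get_vals(baseline_envelope)) else NA_real_
  if (!is.na(base)) {
    assert_that(mvc_ref > base, "MVC reference does not exceed baseline")
  } else {
    assert_that(mvc_ref > 0, "MVC reference must be positive")
  }
  tibble::tibble(
    activity_pct = 100 * mean(env) / mvc_ref,
    mvc_reference_uv = mvc_ref,
    baseline_uv = base
  )
}
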