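#' Single-lead ECG signal record
#'
#' Lightweight container for one lead of an ECG recording, with amplitudes in
#' millivolts and a sampling rate in samples per second.  Sample positions
#' throughout the package are 1-based indices; the time of sample `i` is
#' `(i - 1) / fs` seconds.
#'
#' @param samples numeric vector of amplitudes (mV); must be finite.
#' @param fs sampling rate in samples/s (> 0).
#' @param record_id identifier of the recording.
#' @param lead_name name of the lead (e.g. `"MLII"`, `"V5"`, `"CSV"`).
#' @return An object of class `"signal_record"`.
#' @export
signal_record <- function(samples, fs, record_id = "record", lead_name = "ECG") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(record_id = as.character(record_id), fs = fs,
                 samples = samples, lead_name = as.character(lead_name),
                 length = length(samples)),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("ECG record '%s', lead %s: %d samples @ %g Hz (%.1f s)\n",
              x$record_id, x$lead_name, x$length, x$fs, x$length / x$fs))
  invisible(x)
}

#' @export
length.signal_record <- function(x) x$length

#' Split a signal into refreshed sliding windows
#'
#' A `window_s`-second window slides over the signal in `step_s`-second steps,
#' emulating a monitor that refreshes its buffer every second.  A trailing
#' remainder shorter than one window is dropped.
#'
#' @param x a [signal_record()] or a numeric vector of samples.
#' @param fs sampling rate; taken from `x` when it is a `signal_record`.
#' @param window_s window length in seconds (default 2 s, long enough to hold
#'   one full cardiac cycle down to 30 beats/min).
#' @param step_s refresh step in seconds.
#' @return A list of `"ecg_window"` objects, each holding `window_s * fs`
#'   samples and the (1-based) global index of its first sample.
#' @export
refresh_windows <- function(x, fs = NULL, window_s = 2.0, step_s = 1.0) {
  if (inherits(x, "signal_record")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("fs is required when x is a plain vector")
  win_n <- round(window_s * fs)
  step_n <- round(step_s * fs)
  if (win_n < 1L || step_n < 1L) stop("window and step must span at least one sample")
  n <- length(x)
  if (n < win_n)
    stop(sprintf("signal (%d samples) shorter than one %g-s window (%d samples)",
                 n, window_s, win_n))
  starts <- seq.int(1L, n - win_n + 1L, by = step_n)
  lapply(starts, function(s)
    ecg_window(x[s:(s + win_n - 1L)], fs = fs, global_start = s))
}

#' @rdname refresh_windows
#' @param samples window samples (mV).
#' @param global_start 1-based index of the window's first sample in the
#'   full record.
#' @export
ecg_window <- function(samples, fs, global_start = 1L) {
  structure(list(samples = as.numeric(samples), fs = fs,
                 global_start = as.integer(global_start),
                 duration = length(samples) / fs),
            class = "ecg_window")
}

#' Causal Butterworth band-pass filter
#'
#' Second-order Butterworth band-pass (two poles per band edge), applied
#' causally with [signal::filter()] so that the method remains usable sample
#' by sample in real time; no zero-phase (forward-backward) pass is applied.
#' The default 0.5--17 Hz band removes baseline drift and high-frequency noise
#' ahead of the enhancement mask; a wider 0.5--40 Hz copy (see
#' `morph_high_hz` in [detector_config()]) preserves QRS amplitude ratios for
#' morphology analysis.
#'
#' @param x numeric vector of samples (mV).
#' @param fs sampling rate (samples/s); must exceed twice the upper band edge.
#' @param low_hz,high_hz band edges in Hz.
#' @param order filter order per band edge (default 2).
#' @return Filtered samples, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low_hz = 0.5, high_hz = 17, order = 2L) {
  if (fs <= 2 * high_hz)
    stop(sprintf("fs = %g too low for a %g Hz band edge", fs, high_hz))
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filter(bf, as.numeric(x)))
}

#' QRS enhancement mask
#'
#' Zero-sum mask of length `2k + 1` with value `2k` at its center and `-1`
#' elsewhere.  Convolved with the filtered ECG it amplifies sharp deflections
#' (QRS complexes) while annihilating constant and, for `k = 1`, exactly
#' annihilating linear trends -- which is what removes baseline wander and
#' restrains the slow P and T waves.
#'
#' @param k mask half-width (positive integer).
#' @return Numeric vector of `2k + 1` mask coefficients summing to zero.
#' @examples
#' enhancement_mask(1)  # c(-1, 2, -1)
#' @export
enhancement_mask <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be a positive integer")
  c(rep(-1, k), 2 * k, rep(-1, k))
}

#' Apply the enhancement mask to a sample vector
#'
#' Computes `S(n) = sum_{j=-k..k} M(k+j) E(n+j)` for every interior sample.
#' The `k` edge samples at each end, where the mask would reach outside the
#' window, are set to zero and excluded from the valid range (no zero padding,
#' which would create spurious edge crests).
#'
#' @param x numeric vector (filtered ECG samples).
#' @param k mask half-width.
#' @return Numeric vector the same length as `x`; entries outside
#'   `[k + 1, length(x) - k]` are zero.
#' @export
apply_mask <- function(x, k = 1L) {
  k <- as.integer(k)
  n <- length(x)
  if (n <= 2L * k) stop("input must be longer than the mask (2k + 1 samples)")
  m <- enhancement_mask(k)
  s <- as.numeric(stats::filter(as.numeric(x), rev(m), method = "convolution",
                                sides = 2))
  s[is.na(s)] <- 0
  s
}

#' Transform a window: enhancement mask plus per-window normalization
#'
#' Applies the zero-sum enhancement mask to a (band-pass filtered) window and
#' normalizes the result so that its largest absolute value over the valid
#' sample range equals 1.  Normalization is per window and sign-preserving, so
#' inverted-QRS windows keep their dominant troughs and the crest/trough
#' thresholds of [detector_config()] work across subjects and gain settings.
#' A window whose masked signal is (numerically) all zero carries no QRS-like
#' activity and is returned flagged as rejected.
#'
#' @param window an [ecg_window()] (band-pass filtered samples).
#' @param k mask half-width.
#' @return An object of class `"transformed_window"` with fields `values`
#'   (normalized, zero outside the valid range), `valid_lo`/`valid_hi`
#'   (1-based inclusive bounds of the valid range), `k`, `fs`, `global_start`,
#'   `scale` (the normalization divisor, in mV), and `rejected`.
#' @export
transform_window <- function(window, k = 1L) {
  stopifnot(inherits(window, "ecg_window"))
  k <- as.integer(k)
  e <- window$samples
  n <- length(e)
  if (n <= 2L * k) stop("window must be longer than 2k samples")
  s <- apply_mask(e, k)
  valid_lo <- k + 1L
  valid_hi <- n - k
  mx <- max(abs(s[valid_lo:valid_hi]))
  # relative tolerance: a masked signal this small is numerically zero
  tol <- 1e-9 * max(1, max(abs(e)))
  rejected <- mx <= tol
  values <- if (rejected) rep(0, n) else s / mx
  structure(list(values = values, k = k, valid_lo = valid_lo,
                 valid_hi = valid_hi, fs = window$fs,
                 global_start = window$global_start,
                 scale = mx, rejected = rejected),
            class = "transformed_window")
}

#' @export
print.transformed_window <- function(x, ...) {
  cat(sprintf("Transformed window @ sample %d: %d samples, k = %d, %s\n",
              x$global_start, length(x$values), x$k,
              if (x$rejected) "rejected (no QRS-like activity)"
              else sprintf("scale %.4g mV", x$scale)))
  invisible(x)
}
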