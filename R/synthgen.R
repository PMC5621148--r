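# Seeded synthetic single-lead ECG generator with ground truth.  Beats are
# sums of Gaussian components (P, QRS deflections, T); the component tables
# below define lead-II-like versions of the four supported QRS morphologies
# plus inverted-QRS and large-P variants.  Gaussian synthesis keeps the truth
# placement exact and the waveform geometry transparent.

# component tables: center (s, relative to the dominant QRS deflection),
# width (Gaussian sigma, s), amplitude (relative units; rescaled so the
# waveform's largest |value| equals amp_mv)
.TEMPLATE_COMPONENTS <- list(
  # normal QRS: dominant R crest with small Q/S dips
  a = rbind(P = c(-0.220, 0.030, 0.12),
            Q = c(-0.042, 0.012, -0.12),
            R = c( 0.000, 0.014, 1.00),
            S = c( 0.045, 0.016, -0.18),
            T = c( 0.280, 0.065, 0.30)),
  # fork-like crests: wide R bump carved by a sharp mid-QRS notch (rsR')
  b = rbind(P = c(-0.200, 0.030, 0.10),
            R = c( 0.000, 0.040, 1.00),
            notch = c(0.004, 0.012, -0.70),
            T = c( 0.320, 0.070, 0.40)),
  # deep S wave with small R wave, discordant upright T
  c = rbind(P = c(-0.240, 0.030, 0.10),
            R = c(-0.038, 0.014, 0.22),
            S = c( 0.005, 0.016, -1.00),
            T = c( 0.200, 0.055, 0.32)),
  # deep S wave with tiny/hidden R wave (QS), discordant upright T
  d = rbind(P = c(-0.220, 0.030, 0.10),
            QS = c(0.000, 0.020, -1.00),
            T = c( 0.150, 0.055, 0.28)),
  # inverted QRS (negative dominant deflection), discordant upright T
  inverted = rbind(P = c(-0.200, 0.030, 0.12),
                   R = c( 0.000, 0.014, -1.00),
                   T = c( 0.150, 0.055, 0.30)),
  # normal QRS with a large P wave
  bigP = rbind(P = c(-0.220, 0.030, 0.45),
               Q = c(-0.042, 0.012, -0.12),
               R = c( 0.000, 0.014, 1.00),
               S = c( 0.045, 0.016, -0.18),
               T = c( 0.280, 0.065, 0.30))
)

# which sample carries the ground-truth R: the dominant positive apex for
# upright templates, the dominant trough for deep-S/inverted ones (matching
# the detector's own output convention, so clean-signal evaluation is fair)
.TRUTH_POLARITY <- c(a = "max", b = "max", c = "min", d = "min",
                     inverted = "min", bigP = "max")

#' Synthetic beat waveform
#'
#' Builds one beat of the requested morphology as a sum of Gaussian
#' components, sampled at `fs`, spanning 0.40 s before to 0.50 s after the
#' dominant QRS deflection.  The waveform is rescaled so its largest absolute
#' amplitude equals `amp_mv`.
#'
#' @param kind one of `"a"` (normal QRS), `"b"` (fork-like crests), `"c"`
#'   (deep S, small R), `"d"` (deep S, tiny/hidden R), `"inverted"`
#'   (negative dominant deflection), `"bigP"` (normal QRS, large P wave).
#' @param fs sampling rate (>= 120 samples/s).
#' @param amp_mv dominant-deflection amplitude in mV (> 0).
#' @return A list with `wave` (numeric vector, mV), `r_offset` (1-based index
#'   of the ground-truth R sample within `wave`), and `kind`.
#' @export
beat_template <- function(kind = c("a", "b", "c", "d", "inverted", "bigP"),
                          fs = 360, amp_mv = 1.0) {
  kind <- match.arg(kind)
  if (amp_mv <= 0) stop("amp_mv must be positive")
  if (fs < 120) stop("fs must be at least 120 samples/s")
  comp <- .TEMPLATE_COMPONENTS[[kind]]
  t <- seq(-0.40, 0.50, by = 1 / fs)
  wave <- rep(0, length(t))
  for (i in seq_len(nrow(comp)))
    wave <- wave + comp[i, 3] * exp(-(t - comp[i, 1])^2 / (2 * comp[i, 2]^2))
  wave <- wave * (amp_mv / max(abs(wave)))
  r_offset <- if (.TRUTH_POLARITY[[kind]] == "max") which.max(wave)
              else which.min(wave)
  list(wave = wave, r_offset = r_offset, kind = kind)
}

#' Generate a synthetic single-lead ECG with ground truth
#'
#' Places one beat per RR-interval entry at cumulative RR times, then adds an
#' optional sinusoidal baseline wander and seeded white Gaussian noise.  The
#' ground truth (R sample indices and template kinds) is recorded before any
#' noise is added.  RR intervals must lie in the supported 30--240 beats/min
#' operating envelope, i.e. 0.25--2.0 s.
#'
#' @param rr_s numeric vector of RR intervals in seconds; beat `i` is placed
#'   `sum(rr_s[1..i-1])` after the first beat, so `length(rr_s)` beats are
#'   generated.
#' @param kinds per-beat morphology kinds (recycled; see [beat_template()]).
#' @param fs sampling rate.
#' @param amp_mv dominant QRS amplitude in mV.
#' @param wander `NULL`, or `c(freq_hz, amp_mv)` of a sinusoidal baseline
#'   wander.
#' @param noise_rms_mv standard deviation of additive white Gaussian noise.
#' @param seed integer seed for the noise generator (same seed, same signal).
#' @return An object of class `"synthetic_record"`: a list with `signal`
#'   (a [signal_record()]), `truth_r` (1-based R sample indices),
#'   `truth_template` (per-beat kinds), `rr_schedule`, and `seed`.
#' @export
generate_ecg <- function(rr_s, kinds = "a", fs = 360, amp_mv = 1.0,
                         wander = NULL, noise_rms_mv = 0, seed = NULL) {
  rr_s <- as.numeric(rr_s)
  if (!length(rr_s)) stop("rr_s must contain at least one RR interval")
  if (any(rr_s < 0.25 | rr_s > 2.0))
    stop("RR intervals must lie in [0.25, 2.0] s (30-240 beats/min)")
  n_beats <- length(rr_s)
  kinds <- rep_len(as.character(kinds), n_beats)
  beat_t <- 0.5 + c(0, cumsum(rr_s[-n_beats]))   # 0.5 s lead-in
  dur <- beat_t[n_beats] + 1.0
  n <- round(dur * fs)
  sig <- rep(0, n)
  truth_r <- integer(n_beats)
  for (i in seq_len(n_beats)) {
    bt <- beat_template(kinds[i], fs = fs, amp_mv = amp_mv)
    r_sample <- round(beat_t[i] * fs) + 1L
    start <- r_sample - bt$r_offset + 1L
    idx <- start:(start + length(bt$wave) - 1L)
    ok <- idx >= 1L & idx <= n
    sig[idx[ok]] <- sig[idx[ok]] + bt$wave[ok]
    truth_r[i] <- r_sample
  }
  if (!is.null(wander)) {
    if (length(wander) != 2) stop("wander must be c(freq_hz, amp_mv)")
    tt <- (seq_len(n) - 1) / fs
    sig <- sig + wander[2] * sin(2 * pi * wander[1] * tt)
  }
  if (noise_rms_mv > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- sig + stats::rnorm(n, sd = noise_rms_mv)
  }
  structure(list(signal = signal_record(sig, fs = fs, record_id = "synthetic",
                                        lead_name = "synthII"),
                 truth_r = truth_r, truth_template = kinds,
                 rr_schedule = rr_s, seed = seed),
            class = "synthetic_record")
}

#' Convenience constant-rate synthesis
#'
#' @param n_beats number of beats.
#' @param bpm constant heart rate in beats/min.
#' @param ... passed to [generate_ecg()].
#' @return A `"synthetic_record"` (see [generate_ecg()]).
#' @export
synth_ecg <- function(n_beats = 60, bpm = 75, ...) {
  generate_ecg(rep(60 / bpm, n_beats), ...)
}

#' @export
print.synthetic_record <- function(x, ...) {
  cat(sprintf("Synthetic ECG: %d beats (%s) @ %g Hz, %.1f s\n",
              length(x$truth_r),
              paste(unique(x$truth_template), collapse = "/"),
              x$signal$fs, x$signal$length / x$signal$fs))
  invisible(x)
}
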