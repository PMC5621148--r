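#' Detector configuration
#'
#' Bundles every threshold and time span that governs QRS detection and
#' R-point recognition.  The defaults are the published operating point of the
#' method: static crest/trough thresholds on the normalized transformed signal
#' (0.22 / -0.2, plus a 0.52 "tall lone crest" threshold), a 0.3 s fiducial
#' searching range, a 0.12 s nominal QRS duration, a 0.5 mV activation gate on
#' the window's peak-to-peak amplitude, a 0.24 s Q/R/S searching span centered
#' at the fiducial point, and the 150 ms EC57 beat-pairing tolerance.
#'
#' @param pos_thr positive threshold on the normalized transformed signal above
#'   which a run of samples forms a crest.
#' @param neg_thr negative threshold below which a run forms a trough.
#' @param high_thr threshold a lone crest must exceed to be accepted as a
#'   fiducial point on its own (state-machine Case III).
#' @param search_range_s fiducial searching range in seconds.
#' @param qrs_dur_s nominal QRS duration in seconds; used as the skip-ahead
#'   after Case II/III fiducials.
#' @param min_amp_mv activation gate: a window is only processed when its
#'   filtered peak-to-peak range strictly exceeds this amplitude (mV).
#' @param rspan_s width of the Q/R/S searching span (seconds), centered at the
#'   fiducial point.
#' @param match_tol_s pairing tolerance (seconds) for beat-by-beat comparison
#'   and for cross-window deduplication.
#' @param band_low_hz,band_high_hz band edges (Hz) of the filter feeding the
#'   enhancement mask.
#' @param morph_high_hz upper band edge (Hz) of the morphology copy used for
#'   Q/Ra/R/S localization.
#' @param k half-width of the enhancement mask (mask length is `2k + 1`).
#' @param window_s,step_s sliding-window length and refresh step (seconds).
#'
#' @return An object of class `"detector_config"` (a validated list).
#' @examples
#' cfg <- detector_config()
#' cfg$pos_thr
#' @export
detector_config <- function(pos_thr = 0.22, neg_thr = -0.2, high_thr = 0.52,
                            search_range_s = 0.3, qrs_dur_s = 0.12,
                            min_amp_mv = 0.5, rspan_s = 0.24,
                            match_tol_s = 0.15,
                            band_low_hz = 0.5, band_high_hz = 17,
                            morph_high_hz = 40,
                            k = 1L, window_s = 2.0, step_s = 1.0) {
  cfg <- list(pos_thr = pos_thr, neg_thr = neg_thr, high_thr = high_thr,
              search_range_s = search_range_s, qrs_dur_s = qrs_dur_s,
              min_amp_mv = min_amp_mv, rspan_s = rspan_s,
              match_tol_s = match_tol_s,
              band_low_hz = band_low_hz, band_high_hz = band_high_hz,
              morph_high_hz = morph_high_hz,
              k = as.integer(k), window_s = window_s, step_s = step_s)
  if (!(cfg$neg_thr < 0 && 0 < cfg$pos_thr && cfg$pos_thr < cfg$high_thr &&
        cfg$high_thr <= 1))
    stop("thresholds must satisfy neg_thr < 0 < pos_thr < high_thr <= 1")
  spans <- c(cfg$search_range_s, cfg$qrs_dur_s, cfg$rspan_s, cfg$match_tol_s,
             cfg$window_s, cfg$step_s)
  if (any(!is.finite(spans)) || any(spans <= 0))
    stop("all time spans must be positive")
  if (cfg$k < 1L) stop("mask half-width k must be >= 1")
  if (!(0 < cfg$band_low_hz && cfg$band_low_hz < cfg$band_high_hz &&
        cfg$band_high_hz <= cfg$morph_high_hz))
    stop("band edges must satisfy 0 < band_low_hz < band_high_hz <= morph_high_hz")
  if (cfg$min_amp_mv < 0) stop("min_amp_mv must be >= 0")
  structure(cfg, class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat("QRS detector configuration\n")
  cat(sprintf("  crest/trough thresholds : %+0.2f / %+0.2f (lone crest %0.2f)\n",
              x$pos_thr, x$neg_thr, x$high_thr))
  cat(sprintf("  searching range / QRS   : %0.2f s / %0.2f s\n",
              x$search_range_s, x$qrs_dur_s))
  cat(sprintf("  activation gate         : %0.2f mV peak-to-peak\n", x$min_amp_mv))
  cat(sprintf("  Q/R/S span              : %0.2f s centered at fiducial\n", x$rspan_s))
  cat(sprintf("  mask half-width k       : %d\n", x$k))
  cat(sprintf("  filters                 : %0.1f-%0.1f Hz (mask), %0.1f-%0.1f Hz (morphology)\n",
              x$band_low_hz, x$band_high_hz, x$band_low_hz, x$morph_high_hz))
  cat(sprintf("  window / refresh        : %0.1f s / %0.1f s\n", x$window_s, x$step_s))
  invisible(x)
}
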