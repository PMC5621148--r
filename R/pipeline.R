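#' End-to-end QRS detection on a record
#'
#' Runs the full detector: the record is band-pass filtered once (0.5--17 Hz
#' for the enhancement mask, 0.5--40 Hz for morphology analysis), split into
#' refreshed 2-s windows, and each active window is transformed, scanned for
#' fiducial points, and its beats recognized.  The first window reports beats
#' from its full length; every later window reports only beats from its newer
#' `step_s` second(s), extended backwards by one searching range to cover
#' beats the previous window deferred at its edge.  Residual duplicates from
#' the window overlap are merged with [deduplicate_beats()].
#'
#' @param record a [signal_record()] at least one window long.
#' @param cfg a [detector_config()].
#' @return An object of class `"detection_run"`: a list with `beats` (data
#'   frame of per-beat features sorted by R time -- columns `q`, `ra`, `r`,
#'   `s`, `template`, `case_label`, `fiducial`, `r_time`), `record_id`, `fs`
#'   and `config`.
#' @export
detect_beats <- function(record, cfg = detector_config()) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$fs
  band <- bandpass_filter(record$samples, fs, cfg$band_low_hz, cfg$band_high_hz)
  morph <- bandpass_filter(record$samples, fs, cfg$band_low_hz, cfg$morph_high_hz)
  windows <- refresh_windows(band, fs = fs, window_s = cfg$window_s,
                             step_s = cfg$step_s)
  win_n <- round(cfg$window_s * fs)
  step_n <- round(cfg$step_s * fs)
  # beats whose searching range overruns a window's end are deferred to the
  # next window, where they sit up to one searching range before the newer
  # step_s segment -- the reporting slack must cover that zone
  slack_n <- round(cfg$search_range_s * fs)

  beats <- list()
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    if (!activation_check(w, cfg)) next
    tw <- transform_window(w, cfg$k)
    if (tw$rejected) next
    fids <- detect_fiducials(tw, cfg, at_record_end = (wi == length(windows)))
    if (!nrow(fids)) next
    if (wi > 1L) {
      keep_from <- w$global_start + (win_n - step_n) - slack_n
      fids <- fids[fids$global >= keep_from, , drop = FALSE]
    }
    if (!nrow(fids)) next
    rows <- lapply(seq_len(nrow(fids)), function(i)
      recognize_beat(morph, fids$global[i], fs, fids$case_label[i], cfg))
    beats[[length(beats) + 1L]] <- do.call(rbind, rows)
  }
  beats <- if (length(beats)) do.call(rbind, beats) else
    data.frame(q = integer(0), ra = integer(0), r = integer(0),
               s = integer(0), template = character(0),
               case_label = character(0), fiducial = integer(0),
               r_time = numeric(0))
  beats <- deduplicate_beats(beats, cfg, fs)
  structure(list(beats = beats, record_id = record$record_id, fs = fs,
                 config = cfg),
            class = "detection_run")
}

#' Merge duplicate detections from overlapping windows
#'
#' Beats whose R times differ by less than `match_tol_s` collapse to one; the
#' beat detected in the earlier window (earlier in the input order) wins.
#' 150 ms reuses the EC57 pairing radius: no physiological beat pair is
#' closer even at the 240 beats/min ceiling (250 ms RR interval).
#'
#' @param beats data frame of beat features in window-processing order, with
#'   at least an `r_time` column (seconds).
#' @param cfg a [detector_config()].
#' @param fs sampling rate (unused, kept for interface symmetry).
#' @return The deduplicated data frame, sorted by `r_time`.
#' @export
deduplicate_beats <- function(beats, cfg = detector_config(), fs = NULL) {
  if (!nrow(beats)) return(beats)
  keep_times <- numeric(0)
  keep <- logical(nrow(beats))
  for (i in seq_len(nrow(beats))) {
    t <- beats$r_time[i]
    if (!length(keep_times) || all(abs(keep_times - t) >= cfg$match_tol_s)) {
      keep[i] <- TRUE
      keep_times <- c(keep_times, t)
    }
  }
  out <- beats[keep, , drop = FALSE]
  out <- out[order(out$r_time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.detection_run <- function(x, ...) {
  n <- nrow(x$beats)
  cat(sprintf("QRS detection run on '%s': %d beats @ %g Hz\n",
              x$record_id, n, x$fs))
  if (n > 1) {
    rri <- diff(x$beats$r_time)
    cat(sprintf("  mean RR %.3f s (%.1f bpm); templates: %s\n",
                mean(rri), 60 / mean(rri),
                paste(sprintf("%s=%d", names(table(x$beats$template)),
                              as.integer(table(x$beats$template))),
                      collapse = " ")))
  }
  invisible(x)
}
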