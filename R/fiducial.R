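#' Crest and trough detection on the transformed signal
#'
#' Because the transformed window is normalized to 1, static thresholds work:
#' every maximal run of consecutive samples above `pos_thr` contributes one
#' crest (its maximum sample, earliest index on ties), and every run below
#' `neg_thr` contributes one trough (its minimum sample).  Reducing each run
#' to one extremum prevents sample-level jitter from splitting a single wave
#' into several crests.  Only the valid (mask-covered) sample range is
#' scanned.
#'
#' @param tw a [transform_window()] result (not rejected).
#' @param cfg a [detector_config()].
#' @return A data frame with one row per extremum, sorted by index: `index`
#'   (local, 1-based), `value`, `polarity` (`"crest"`/`"trough"`), and
#'   `onset`/`end` (bounds of the supra-threshold run).
#' @export
find_extrema <- function(tw, cfg = detector_config()) {
  stopifnot(inherits(tw, "transformed_window"))
  if (tw$rejected) stop("cannot search extrema in a rejected window")
  v <- tw$values
  idx <- tw$valid_lo:tw$valid_hi
  one_side <- function(flag, pick) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep))
      return(data.frame(index = integer(0), value = numeric(0),
                        onset = integer(0), end = integer(0)))
    peak <- vapply(keep, function(m) {
      seg <- idx[starts[m]:ends[m]]
      seg[pick(v[seg])]           # which.max/which.min: earliest on ties
    }, integer(1))
    data.frame(index = peak, value = v[peak],
               onset = idx[starts[keep]], end = idx[ends[keep]])
  }
  crests <- one_side(v[idx] > cfg$pos_thr, which.max)
  troughs <- one_side(v[idx] < cfg$neg_thr, which.min)
  out <- rbind(cbind(crests, polarity = rep("crest", nrow(crests))),
               cbind(troughs, polarity = rep("trough", nrow(troughs))))
  out[order(out$index), , drop = FALSE]
}

#' Window activation gate
#'
#' A refreshed window is only analyzed when its filtered peak-to-peak range
#' strictly exceeds the minimum QRS amplitude (0.5 mV by default); flat or
#' disconnected-electrode segments are skipped.
#'
#' @param window an [ecg_window()] of filtered samples (mV).
#' @param cfg a [detector_config()].
#' @return `TRUE` if the window should be processed.
#' @export
activation_check <- function(window, cfg = detector_config()) {
  stopifnot(inherits(window, "ecg_window"))
  rng <- range(window$samples)
  (rng[2] - rng[1]) > cfg$min_amp_mv
}

#' Four-case QRS fiducial point detection
#'
#' Scans the transformed window forward.  The starting point is the first
#' sample whose value exceeds `pos_thr` (the onset of a crest run); the
#' crests and troughs whose extremum falls within the searching range
#' `[start, start + search_range_s)` are then examined:
#'
#' * **Case I** -- exactly one crest and exactly one trough: the crest is the
#'   fiducial point; the scan resumes just after the trough.
#' * **Case II** -- exactly two crests and exactly one trough lying between
#'   them: the trough is the fiducial point (fork-like and inverted QRS);
#'   the scan resumes one QRS duration (0.12 s) after the trough.
#' * **Case III** -- exactly one crest, no trough, crest value above
#'   `high_thr`: the lone tall crest is the fiducial point; the scan resumes
#'   one QRS duration after it.
#' * **Case IV** (otherwise) -- the starting point is redefined as the onset
#'   of the next crest after the first crest in range.
#'
#' A starting point whose searching range would extend past the window's
#' valid end is deferred: with a 1-s refresh step the same beat reappears
#' fully covered in the next window.  In the last window of a record no
#' future window exists, so `at_record_end = TRUE` clips the searching range
#' at the valid end instead of deferring.
#'
#' @param tw a [transform_window()] result.
#' @param cfg a [detector_config()].
#' @param at_record_end set to `TRUE` for the final window of a record.
#' @return A data frame with one row per fiducial point: `index` (local,
#'   1-based), `global` (index in the full record), `case_label`
#'   (`"I"`/`"II"`/`"III"`) and `source` (`"crest"`/`"trough"`).
#' @export
detect_fiducials <- function(tw, cfg = detector_config(), at_record_end = FALSE) {
  stopifnot(inherits(tw, "transformed_window"))
  empty <- data.frame(index = integer(0), global = integer(0),
                      case_label = character(0), source = character(0))
  if (tw$rejected) return(empty)
  ex <- find_extrema(tw, cfg)
  crest_runs <- ex[ex$polarity == "crest", , drop = FALSE]
  troughs <- ex[ex$polarity == "trough", , drop = FALSE]
  if (!nrow(crest_runs)) return(empty)

  fs <- tw$fs
  range_n <- round(cfg$search_range_s * fs)
  qrs_n <- round(cfg$qrs_dur_s * fs)
  pos <- tw$valid_lo
  out_idx <- integer(0)
  out_case <- character(0)
  out_src <- character(0)

  repeat {
    ri <- which(crest_runs$end >= pos)
    if (!length(ri)) break
    run1 <- crest_runs[ri[1], ]
    start <- max(run1$onset, pos)
    rng_hi <- start + range_n - 1L
    if (rng_hi > tw$valid_hi) {
      if (!at_record_end) break  # defer to next window
      if (start > tw$valid_hi) break
      rng_hi <- tw$valid_hi
    }
    cr <- crest_runs[crest_runs$index >= start & crest_runs$index <= rng_hi, ]
    trg <- troughs[troughs$index >= start & troughs$index <= rng_hi, ]
    nc <- nrow(cr)
    nt <- nrow(trg)

    fid <- NA_integer_
    case <- NA_character_
    src <- NA_character_
    if (nc == 1L && nt == 1L) {
      fid <- cr$index; case <- "I"; src <- "crest"
      pos_new <- trg$index + 1L
    } else if (nc == 2L && nt == 1L &&
               trg$index > cr$index[1] && trg$index < cr$index[2]) {
      fid <- trg$index; case <- "II"; src <- "trough"
      pos_new <- trg$index + qrs_n
    } else if (nc == 1L && nt == 0L && cr$value > cfg$high_thr) {
      fid <- cr$index; case <- "III"; src <- "crest"
      pos_new <- cr$index + qrs_n
    } else {
      # Case IV: restart at the onset of the next crest after the first crest
      ref <- if (nc >= 1L) cr$index[1] else start
      nxt <- crest_runs$onset[crest_runs$onset > ref]
      if (!length(nxt)) break
      pos_new <- nxt[1]
    }
    if (!is.na(fid) &&
        (!length(out_idx) || fid > out_idx[length(out_idx)])) {
      out_idx <- c(out_idx, fid)
      out_case <- c(out_case, case)
      out_src <- c(out_src, src)
    }
    if (pos_new <= pos) pos_new <- pos + 1L  # guarantee forward progress
    pos <- pos_new
  }
  data.frame(index = out_idx,
             global = tw$global_start + out_idx - 1L,
             case_label = out_case, source = out_src)
}
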