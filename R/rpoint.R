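# Q/Ra/R/S localization around a fiducial point, on the 0.5-40 Hz morphology
# signal.  "Local minimum slope" points are taken as local minima of the
# signal (first difference changes from negative to non-negative): in all four
# supported templates Q and S are wave troughs.

# local maxima / minima over [lo, hi]; boundary samples excluded
.local_maxima <- function(x, lo, hi) {
  if (hi - lo < 2L) return(integer(0))
  i <- (lo + 1L):(hi - 1L)
  i[x[i] > x[i - 1L] & x[i + 1L] <= x[i]]
}

.local_minima <- function(x, lo, hi) {
  if (hi - lo < 2L) return(integer(0))
  i <- (lo + 1L):(hi - 1L)
  i[x[i] < x[i - 1L] & x[i + 1L] >= x[i]]
}

#' Amplitude statistics of the Q/R/S searching span
#'
#' The span is `rspan_s` seconds (0.24 s by default, twice a normal QRS
#' duration) centered at the fiducial point, clipped to the signal bounds at
#' record edges.
#'
#' @param morph numeric vector, the morphology (0.5--40 Hz filtered) signal
#'   in mV.
#' @param fiducial 1-based sample index of the fiducial point.
#' @param fs sampling rate.
#' @param cfg a [detector_config()].
#' @return A list with `lo`, `hi` (1-based inclusive span bounds), `max_amp`
#'   and `mean_amp` (mV).
#' @export
span_stats <- function(morph, fiducial, fs, cfg = detector_config()) {
  n <- length(morph)
  if (fiducial < 1L || fiducial > n) stop("fiducial outside the signal")
  span_n <- round(cfg$rspan_s * fs)
  half <- span_n %/% 2L
  lo <- max(1L, fiducial - half)
  hi <- min(n, lo + span_n - 1L)
  seg <- morph[lo:hi]
  list(lo = lo, hi = hi, max_amp = max(seg), mean_amp = mean(seg))
}

#' S point detection
#'
#' Scans forward from the fiducial point: the S start point is the first
#' local maximum after the fiducial whose amplitude exceeds half the span
#' maximum (the R crest, when one exists), otherwise the fiducial itself.
#' The S point is then the first local minimum after the S start point with
#' amplitude below the span mean; if no such point exists before the span
#' end, the minimum-value sample after the S start point is used.
#'
#' @inheritParams span_stats
#' @param stats result of [span_stats()].
#' @return 1-based sample index of the S point.
#' @export
detect_s <- function(morph, fiducial, stats, cfg = detector_config()) {
  lo <- stats$lo; hi <- stats$hi
  cand <- .local_maxima(morph, lo, hi)
  cand <- cand[cand > fiducial & morph[cand] > stats$max_amp / 2]
  s_start <- if (length(cand)) cand[1] else fiducial
  mins <- .local_minima(morph, lo, hi)
  mins <- mins[mins > s_start & morph[mins] < stats$mean_amp]
  if (length(mins)) return(mins[1])
  if (s_start >= hi) return(s_start)
  after <- (s_start + 1L):hi
  after[which.min(morph[after])]
}

#' Ra (approximate R) point detection
#'
#' If at least one local maximum ahead of the detected S point exceeds half
#' the span maximum, Ra is the maximum-amplitude sample of the span before S
#' (earliest index on ties); otherwise Ra coincides with S (deep-S templates
#' with no usable R crest).
#'
#' @inheritParams detect_s
#' @param s S point index from [detect_s()].
#' @return 1-based sample index of the Ra point.
#' @export
detect_ra <- function(morph, s, stats) {
  lo <- stats$lo
  cand <- .local_maxima(morph, lo, stats$hi)
  cand <- cand[cand < s & morph[cand] > stats$max_amp / 2]
  if (!length(cand) || s <= lo) return(s)
  before <- lo:(s - 1L)
  before[which.max(morph[before])]
}

#' Q point detection
#'
#' Mirror image of [detect_s()], scanning backwards: the Q start point is the
#' last local maximum before Ra with amplitude above half the span maximum,
#' otherwise Ra itself; Q is the last local minimum before the Q start point
#' with amplitude below the span mean, with the minimum-value sample before
#' the Q start point as fallback.
#'
#' @inheritParams detect_s
#' @param ra Ra point index from [detect_ra()].
#' @return 1-based sample index of the Q point.
#' @export
detect_q <- function(morph, ra, stats) {
  lo <- stats$lo
  cand <- .local_maxima(morph, lo, stats$hi)
  cand <- cand[cand < ra & morph[cand] > stats$max_amp / 2]
  q_start <- if (length(cand)) cand[length(cand)] else ra
  mins <- .local_minima(morph, lo, stats$hi)
  mins <- mins[mins < q_start & morph[mins] < stats$mean_amp]
  if (length(mins)) return(mins[length(mins)])
  if (q_start <= lo) return(q_start)
  before <- lo:(q_start - 1L)
  before[which.min(morph[before])]
}

#' R point resolution and template assignment
#'
#' * **Case 1**: Ra and S coincide (no usable R crest) -- R is S; template
#'   `"d"` (deep S wave with tiny or hidden R wave).
#' * **Case 2**: the amplitude between Ra and Q is less than a quarter of the
#'   amplitude between Ra and S (absolute differences) -- R is S; template
#'   `"c"` (deep S wave with small R wave).
#' * **Case 3**: otherwise R is Ra; template `"b"` (fork-like crests) when
#'   the fiducial came from a Case II trough, else `"a"` (normal QRS).
#'
#' @inheritParams detect_s
#' @param q,ra,s point indices from the preceding detection steps.
#' @param fiducial_case state-machine case label of the fiducial
#'   (`"I"`, `"II"` or `"III"`).
#' @return A list with `r` (1-based sample index) and `template`
#'   (`"a"`/`"b"`/`"c"`/`"d"`).
#' @export
resolve_r <- function(morph, q, ra, s, fiducial_case = "I") {
  if (ra == s)
    return(list(r = s, template = "d"))
  if (abs(morph[ra] - morph[q]) < 0.25 * abs(morph[ra] - morph[s]))
    return(list(r = s, template = "c"))
  list(r = ra, template = if (identical(fiducial_case, "II")) "b" else "a")
}

#' Recognize one beat from its fiducial point
#'
#' Orchestrates the per-beat feature search: span statistics, then S, Ra, Q
#' and finally R with its template label.  Always returns a beat for a valid
#' fiducial point.
#'
#' @inheritParams span_stats
#' @param fiducial_case state-machine case label (`"I"`, `"II"`, `"III"`).
#' @return A one-row data frame with columns `q`, `ra`, `r`, `s` (1-based
#'   sample indices), `template`, `case_label`, and `r_time` (seconds,
#'   `(r - 1) / fs`).
#' @export
recognize_beat <- function(morph, fiducial, fs, fiducial_case = "I",
                           cfg = detector_config()) {
  st <- span_stats(morph, fiducial, fs, cfg)
  s <- detect_s(morph, fiducial, st, cfg)
  ra <- detect_ra(morph, s, st)
  q <- detect_q(morph, ra, st)
  rr <- resolve_r(morph, q, ra, s, fiducial_case)
  data.frame(q = q, ra = ra, r = rr$r, s = s,
             template = rr$template, case_label = fiducial_case,
             fiducial = fiducial, r_time = (rr$r - 1) / fs)
}
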