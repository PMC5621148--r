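#' Beat-by-beat pairing of detections with reference annotations
#'
#' EC57-style matching: a detection and a reference beat match when the
#' absolute time difference is strictly below the tolerance (150 ms by
#' default).  The pairing is a greedy forward sweep -- each reference beat in
#' order takes the nearest still-unpaired detection within tolerance
#' (earliest detection on ties) -- and is one-to-one.  For physiological beat
#' spacings (references further apart than twice the tolerance) this equals
#' the optimal bipartite pairing.
#'
#' @param detected,reference sorted numeric vectors of beat times (seconds).
#' @param tol_s pairing tolerance in seconds.
#' @return An object of class `"match_report"`: a list with `pairs` (two-column
#'   matrix of reference/detection indices), `unmatched_ref` (FN indices),
#'   `unmatched_det` (FP indices), and `tolerance_s`.
#' @export
match_beats <- function(detected, reference, tol_s = 0.15) {
  if (is.unsorted(detected) || is.unsorted(reference))
    stop("beat time vectors must be sorted")
  nd <- length(detected)
  nr <- length(reference)
  used <- logical(nd)
  pr <- integer(0)
  pd <- integer(0)
  lo <- 1L
  for (i in seq_len(nr)) {
    while (lo <= nd && detected[lo] <= reference[i] - tol_s) lo <- lo + 1L
    j <- lo
    best <- 0L
    best_d <- Inf
    while (j <= nd && detected[j] < reference[i] + tol_s) {
      if (!used[j]) {
        d <- abs(detected[j] - reference[i])
        if (d < tol_s && d < best_d) {   # strict <: ties keep the earliest
          best <- j
          best_d <- d
        }
      }
      j <- j + 1L
    }
    if (best > 0L) {
      used[best] <- TRUE
      pr <- c(pr, i)
      pd <- c(pd, best)
    }
  }
  structure(list(pairs = cbind(ref = pr, det = pd),
                 unmatched_ref = setdiff(seq_len(nr), pr),
                 unmatched_det = which(!used),
                 tolerance_s = tol_s),
            class = "match_report")
}

#' Detector performance metrics
#'
#' Sensitivity `Se = TP / (TP + FN)`, positive predictivity
#' `+P = TP / (TP + FP)` and detection error rate
#' `DER = (FP + FN) / (TP + FN)`, all as percentages.  Raw ratios are
#' retained in the returned object; printing rounds to two decimals.  A zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param tp,fn,fp non-negative counts of true positives, false negatives and
#'   false positives.
#' @return An object of class `"eval_result"`: a list with `TP`, `FN`, `FP`,
#'   `TB` (total beats, `TP + FN`), `Se`, `PPlus`, `DER` (percent, unrounded).
#' @examples
#' compute_metrics(109250, 193, 203)  # Se 99.82, +P 99.81, DER 0.36
#' @export
compute_metrics <- function(tp, fn, fp) {
  if (any(c(tp, fn, fp) < 0)) stop("counts must be non-negative")
  tb <- tp + fn
  se <- if (tb > 0) 100 * tp / tb else NA_real_
  pp <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  der <- if (tb > 0) 100 * (fp + fn) / tb else NA_real_
  structure(list(TP = tp, FN = fn, FP = fp, TB = tb,
                 Se = se, PPlus = pp, DER = der),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.2f%%", v)
  cat(sprintf("Beats: %d (TP %d, FN %d, FP %d)\n", x$TB, x$TP, x$FN, x$FP))
  cat(sprintf("Se %s  +P %s  DER %s\n", fmt(x$Se), fmt(x$PPlus), fmt(x$DER)))
  invisible(x)
}

#' Metrics from a match report
#'
#' @param match a [match_beats()] result.
#' @return An `"eval_result"`.
#' @export
metrics_from_match <- function(match) {
  stopifnot(inherits(match, "match_report"))
  compute_metrics(nrow(match$pairs), length(match$unmatched_ref),
                  length(match$unmatched_det))
}

#' Per-rhythm performance breakdown
#'
#' Attributes each matched / missed reference beat to its annotation code and
#' reports TB, TP, FN and Se per code.  False positives carry no rhythm label
#' and appear only in overall totals.
#'
#' @param match a [match_beats()] result.
#' @param labels character vector of beat-type codes aligned with the
#'   reference beats used for matching.
#' @return A data frame with columns `code`, `TB`, `TP`, `FN`, `Se` (percent),
#'   one row per distinct code in order of first appearance, plus a `Total`
#'   row.
#' @export
per_rhythm <- function(match, labels) {
  stopifnot(inherits(match, "match_report"))
  nr <- nrow(match$pairs) + length(match$unmatched_ref)
  if (length(labels) != nr)
    stop("labels must align with the reference beats (one per beat)")
  matched <- logical(nr)
  matched[match$pairs[, "ref"]] <- TRUE
  codes <- unique(labels)
  rows <- lapply(codes, function(cd) {
    sel <- labels == cd
    tb <- sum(sel)
    tp <- sum(sel & matched)
    data.frame(code = cd, TB = tb, TP = tp, FN = tb - tp,
               Se = if (tb > 0) 100 * tp / tb else NA_real_)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(code = "Total", TB = nr, TP = sum(matched),
                      FN = nr - sum(matched),
                      Se = if (nr > 0) 100 * sum(matched) / nr else NA_real_)
  rbind(out, total)
}

#' Signal-to-noise ratio improvement
#'
#' `SNRimp [dB] = 10 log10( sum |Xn - X|^2 / sum |Xd - X|^2 )`, the output
#' SNR minus the input SNR for a denoising step that maps the noisy signal
#' `Xn` to `Xd`, relative to the clean signal `X`.
#'
#' @param clean,denoised,noisy numeric vectors of equal length.
#' @return Improvement in dB.  `Inf` (with a warning) when the denoised
#'   signal equals the clean signal exactly.
#' @examples
#' x <- sin(seq(0, 10, by = 0.01))
#' snr_improvement(x, x + 0.1, x + 0.2)  # residual energy quartered: ~6 dB
#' @export
snr_improvement <- function(clean, denoised, noisy) {
  if (length(clean) != length(denoised) || length(clean) != length(noisy))
    stop("signals must have equal length")
  num <- sum((noisy - clean)^2)
  den <- sum((denoised - clean)^2)
  if (den == 0) {
    warning("denoised signal equals the clean signal: SNR improvement is infinite")
    return(Inf)
  }
  10 * log10(num / den)
}

#' Evaluate a detection run against reference annotations
#'
#' Applies ventricular-flutter exclusion symmetrically (reference beats and
#' detections falling inside a flutter episode are both removed from the
#' comparison), pairs beats within the EC57 tolerance, and computes the
#' summary metrics and per-rhythm breakdown.
#'
#' @param run a [detect_beats()] result.
#' @param reference a `reference_beats` object (see [read_annotations()]).
#' @param cfg a [detector_config()] (supplies `match_tol_s`).
#' @return A list with `metrics` (an `"eval_result"`), `match` (the
#'   `"match_report"`), and `rhythm` (the per-rhythm data frame).
#' @export
evaluate_run <- function(run, reference, cfg = detector_config()) {
  stopifnot(inherits(run, "detection_run"))
  ref <- exclude_vf(reference)
  det_times <- run$beats$r_time
  if (nrow(ref$vf_episodes)) {
    det_samples <- run$beats$r
    inside <- rep(FALSE, length(det_samples))
    for (e in seq_len(nrow(ref$vf_episodes))) {
      inside <- inside | (det_samples >= ref$vf_episodes[e, 1] &
                          det_samples < ref$vf_episodes[e, 2])
    }
    det_times <- det_times[!inside]
  }
  ref_times <- (ref$times - 1) / run$fs
  m <- match_beats(det_times, ref_times, cfg$match_tol_s)
  list(metrics = metrics_from_match(m), match = m,
       rhythm = per_rhythm(m, ref$labels))
}
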