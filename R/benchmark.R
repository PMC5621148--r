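#' Benchmark the detector over a directory of WFDB records
#'
#' Runs [detect_beats()] and [evaluate_run()] on every record in `db_dir`
#' (or the subset named in `records`) and aggregates the counts, producing a
#' per-record performance table, pooled totals, and a pooled per-rhythm
#' breakdown.  Ventricular flutter/fibrillation episodes are excluded from
#' the comparison on both sides.
#'
#' @param db_dir directory containing `.hea`/`.dat`/`.atr` files.
#' @param records record basenames; default: every `.hea` in `db_dir`.
#' @param lead_preference ordered lead names passed to [read_record()].
#' @param cfg a [detector_config()].
#' @return A list with `per_record` (data frame: `record`, `lead`, `Se`,
#'   `PPlus`, `DER`, `TB`, `FN`, `FP`), `totals` (an `"eval_result"` over the
#'   pooled counts), and `rhythm` (pooled per-code `TB`/`TP`/`FN`/`Se`).
#' @export
benchmark_wfdb <- function(db_dir, records = NULL,
                           lead_preference = c("MLII", "V5"),
                           cfg = detector_config()) {
  if (!dir.exists(db_dir)) stop("no such directory: ", db_dir)
  if (is.null(records)) {
    records <- sort(sub("\\.hea$", "", basename(
      list.files(db_dir, pattern = "\\.hea$", full.names = FALSE))))
  }
  if (!length(records)) stop("no records found in ", db_dir)
  per_rec <- list()
  rhythm_acc <- list()
  tot <- c(TP = 0, FN = 0, FP = 0)
  for (rid in records) {
    rec <- read_record(file.path(db_dir, rid), lead_preference)
    ref <- read_annotations(file.path(db_dir, rid))
    run <- detect_beats(rec, cfg)
    ev <- evaluate_run(run, ref, cfg)
    m <- ev$metrics
    tot <- tot + c(TP = m$TP, FN = m$FN, FP = m$FP)
    per_rec[[rid]] <- data.frame(record = rid, lead = rec$lead_name,
                                 Se = m$Se, PPlus = m$PPlus, DER = m$DER,
                                 TB = m$TB, FN = m$FN, FP = m$FP)
    rh <- ev$rhythm
    rhythm_acc[[rid]] <- rh[rh$code != "Total", c("code", "TB", "TP", "FN")]
  }
  rhythm <- do.call(rbind, rhythm_acc)
  rhythm <- stats::aggregate(cbind(TB, TP, FN) ~ code, data = rhythm, FUN = sum)
  rhythm$Se <- ifelse(rhythm$TB > 0, 100 * rhythm$TP / rhythm$TB, NA_real_)
  list(per_record = do.call(rbind, c(per_rec, list(make.row.names = FALSE))),
       totals = compute_metrics(tot[["TP"]], tot[["FN"]], tot[["FP"]]),
       rhythm = rhythm)
}
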