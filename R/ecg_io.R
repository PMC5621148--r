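# WFDB I/O: header (.hea) parsing, format-212/16 signal decoding, MIT-format
# annotation parsing/writing, plus a plain-CSV dialect.  Amplitudes are
# converted to physical mV via the header gain/baseline; sample indices are
# 1-based.

# beat-type annotation codes (MIT annotation code -> display symbol)
.BEAT_CODES <- c("1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V",
                 "6" = "F", "7" = "J", "8" = "A", "9" = "S", "10" = "E",
                 "11" = "j", "12" = "/", "13" = "Q", "34" = "e", "38" = "f")
.VFON <- 32L   # ventricular flutter/fibrillation episode start marker
.VFOFF <- 33L  # episode end marker

#' Reference beat annotations
#'
#' Container for reference beat times/labels and ventricular flutter or
#' fibrillation (VF) episode intervals, as read from an annotation file.
#'
#' @param times strictly increasing 1-based sample indices of the reference
#'   beats.
#' @param labels beat-type codes (one character per beat, e.g. `"N"`, `"V"`).
#' @param vf_episodes two-column matrix of `[start, end)` sample intervals
#'   (1-based); non-overlapping and sorted.
#' @return An object of class `"reference_beats"`.
#' @export
reference_beats <- function(times = integer(0), labels = character(0),
                            vf_episodes = matrix(numeric(0), ncol = 2)) {
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0))
    stop("beat times must be strictly increasing")
  if (length(labels) != length(times))
    stop("labels must have one entry per beat")
  vf_episodes <- matrix(as.numeric(vf_episodes), ncol = 2)
  colnames(vf_episodes) <- c("start", "end")
  if (nrow(vf_episodes) > 1) {
    o <- order(vf_episodes[, 1])
    vf_episodes <- vf_episodes[o, , drop = FALSE]
    if (any(vf_episodes[-1, 1] < vf_episodes[-nrow(vf_episodes), 2]))
      stop("VF episodes must not overlap")
  }
  structure(list(times = times, labels = as.character(labels),
                 vf_episodes = vf_episodes),
            class = "reference_beats")
}

#' @export
print.reference_beats <- function(x, ...) {
  cat(sprintf("%d reference beats, %d VF episode(s)\n",
              length(x$times), nrow(x$vf_episodes)))
  if (length(x$labels)) {
    tab <- table(x$labels)
    cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = " "), "\n")
  }
  invisible(x)
}

# ---- WFDB header -----------------------------------------------------------

.read_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty or corrupt header: ", hea_path)
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3) stop("corrupt record line in ", hea_path)
  name <- rec[1]
  nsig <- as.integer(rec[2])
  fs <- as.numeric(sub("/.*$", "", rec[3]))  # strip counter-frequency suffix
  nsamp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_
  if (is.na(nsig) || is.na(fs) || nsig < 1 || fs <= 0)
    stop("corrupt record line in ", hea_path)
  if (length(lines) < 1 + nsig) stop("header declares more signals than lines")
  sig <- lapply(lines[2:(1 + nsig)], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 2) stop("corrupt signal line in ", hea_path)
    fmt <- as.integer(sub("x.*$", "", tok[2]))
    gain_tok <- if (length(tok) >= 3) tok[3] else "200"
    units <- if (grepl("/", gain_tok)) sub("^.*/", "", gain_tok) else "mV"
    gb <- sub("/.*$", "", gain_tok)
    baseline <- NA_real_
    if (grepl("\\(", gb)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gb))
      gb <- sub("\\(.*$", "", gb)
    }
    gain <- as.numeric(gb)
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
    adc_zero <- if (length(tok) >= 5) as.numeric(tok[5]) else 0
    if (is.na(baseline)) baseline <- adc_zero
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else NA_character_
    list(file = tok[1], format = fmt, gain = gain, baseline = baseline,
         units = units, description = desc)
  })
  for (i in seq_along(sig))
    if (is.na(sig[[i]]$description)) sig[[i]]$description <- sprintf("sig%d", i - 1L)
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

# ---- signal decoding -------------------------------------------------------

# format 212: 3 bytes hold two 12-bit two's-complement samples
.decode_212 <- function(raw, n_values) {
  nb <- as.integer(raw)
  ntrip <- length(nb) %/% 3L
  b <- matrix(nb[seq_len(3L * ntrip)], nrow = 3L)
  v1 <- b[1, ] + 256L * (b[2, ] %% 16L)
  v2 <- b[3, ] + 256L * (b[2, ] %/% 16L)
  v <- as.vector(rbind(v1, v2))
  v <- ifelse(v > 2047L, v - 4096L, v)
  v[seq_len(min(n_values, length(v)))]
}

# format 16: little-endian 16-bit two's complement
.decode_16 <- function(raw, n_values) {
  v <- readBin(raw, what = "integer", size = 2L, n = n_values,
               signed = TRUE, endian = "little")
  v
}

#' Read a WFDB or CSV record
#'
#' For a WFDB record (a `.hea` header with its signal file), the first lead
#' present in `lead_preference` is selected and its samples are converted to
#' physical mV via the header gain and baseline.  The default preference
#' `c("MLII", "V5")` matches the benchmark convention of using the modified
#' limb lead II where available and V5 otherwise.  Signal formats 212 and 16
#' are supported.  A `.csv` source must have a header row and two columns,
#' time (seconds) and amplitude (mV); the sampling rate is inferred from the
#' time column unless `fs` is given, and the lead is named `"CSV"`.
#'
#' @param source path to a `.hea` header (extension optional) or a `.csv`
#'   file.
#' @param lead_preference ordered character vector of acceptable lead names;
#'   `NULL` selects the first signal in the header.
#' @param fs sampling rate override for CSV sources.
#' @return A [signal_record()].
#' @export
read_record <- function(source, lead_preference = c("MLII", "V5"), fs = NULL) {
  if (grepl("\\.csv$", source, ignore.case = TRUE)) {
    if (!file.exists(source)) stop("missing file: ", source)
    df <- utils::read.csv(source)
    if (ncol(df) < 2) stop("CSV record needs (time, mV) columns")
    tt <- as.numeric(df[[1]])
    mv <- as.numeric(df[[2]])
    if (is.null(fs)) {
      dt <- stats::median(diff(tt))
      if (!is.finite(dt) || dt <= 0) stop("cannot infer fs from time column")
      fs <- 1 / dt
    }
    rec_id <- sub("\\.csv$", "", basename(source), ignore.case = TRUE)
    return(signal_record(mv, fs = fs, record_id = rec_id, lead_name = "CSV"))
  }
  hea_path <- if (grepl("\\.hea$", source)) source else paste0(source, ".hea")
  if (!file.exists(hea_path)) stop("missing file: ", hea_path)
  hdr <- .read_wfdb_header(hea_path)
  leads <- vapply(hdr$signals, `[[`, "", "description")
  ch <- if (is.null(lead_preference)) 1L else {
    hit <- match(lead_preference, leads)
    hit <- hit[!is.na(hit)]
    if (!length(hit))
      stop(sprintf("none of the preferred leads (%s) present; available: %s",
                   paste(lead_preference, collapse = ", "),
                   paste(leads, collapse = ", ")))
    hit[1]
  }
  sig <- hdr$signals[[ch]]
  dat_path <- file.path(dirname(hea_path), sig$file)
  if (!file.exists(dat_path)) stop("missing file: ", dat_path)
  raw <- readBin(dat_path, what = "raw", n = file.info(dat_path)$size)
  n_values <- if (is.finite(hdr$nsamp)) hdr$nsamp * hdr$nsig else NA
  adc <- switch(as.character(sig$format),
                "212" = .decode_212(raw, if (is.na(n_values))
                  (length(raw) %/% 3L) * 2L else n_values),
                "16" = .decode_16(raw, if (is.na(n_values))
                  length(raw) %/% 2L else n_values),
                stop("unsupported WFDB signal format: ", sig$format))
  samples <- adc[seq.int(ch, length(adc), by = hdr$nsig)]
  if (is.finite(hdr$nsamp)) samples <- samples[seq_len(hdr$nsamp)]
  mv <- (samples - sig$baseline) / sig$gain
  signal_record(mv, fs = hdr$fs, record_id = hdr$name, lead_name = leads[ch])
}

# ---- MIT-format annotations ------------------------------------------------

.parse_mit_annotations <- function(raw) {
  nb <- as.integer(raw)
  i <- 1L
  t <- 0
  times <- numeric(0)
  codes <- integer(0)
  n_bytes <- length(nb)
  while (i + 1L <= n_bytes) {
    b1 <- nb[i]; b2 <- nb[i + 1L]; i <- i + 2L
    code <- b2 %/% 4L
    interval <- (b2 %% 4L) * 256L + b1
    if (code == 0L && interval == 0L) break          # EOF
    if (code == 59L) {                               # SKIP: 4-byte interval
      if (i + 3L > n_bytes) stop("truncated SKIP in annotation stream")
      w1 <- nb[i] + 256 * nb[i + 1L]                 # high word first
      w2 <- nb[i + 2L] + 256 * nb[i + 3L]
      i <- i + 4L
      skip <- w1 * 65536 + w2
      if (skip >= 2^31) skip <- skip - 2^32
      t <- t + skip
    } else if (code == 63L) {                        # AUX: skip payload
      nbyte <- interval
      i <- i + nbyte + (nbyte %% 2L)
    } else if (code %in% c(60L, 61L, 62L)) {         # NUM/SUB/CHN attributes
      # no time advance
    } else {
      t <- t + interval
      times <- c(times, t)
      codes <- c(codes, code)
    }
  }
  list(times = times, codes = codes)
}

#' Read MIT-format beat annotations
#'
#' Parses an MIT-format annotation file into beat times and labels.  Beat
#' annotations keep their display symbols (`N`, `L`, `R`, `A`, `a`, `J`, `S`,
#' `V`, `F`, `e`, `j`, `E`, `/`, `f`, `Q`); ventricular flutter/fibrillation
#' episodes are delimited by the database's flutter start/end markers and
#' returned as `[start, end)` intervals; all other non-beat annotations are
#' dropped.  An unclosed episode extends to the end of the stream (`Inf`).
#'
#' @param source path to the annotation file; when the path has no file
#'   extension, `.atr` is appended.
#' @return A [reference_beats()].
#' @export
read_annotations <- function(source) {
  path <- if (grepl("\\.[A-Za-z0-9]+$", basename(source))) source
          else paste0(source, ".atr")
  if (!file.exists(path)) stop("missing file: ", path)
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  ann <- .parse_mit_annotations(raw)
  is_beat <- as.character(ann$codes) %in% names(.BEAT_CODES)
  beat_times <- ann$times[is_beat] + 1            # 0-based file -> 1-based
  labels <- unname(.BEAT_CODES[as.character(ann$codes[is_beat])])
  # VF episodes from flutter start/end markers
  ep_open <- NA_real_
  eps <- NULL
  for (j in seq_along(ann$codes)) {
    if (ann$codes[j] == .VFON && is.na(ep_open)) ep_open <- ann$times[j] + 1
    if (ann$codes[j] == .VFOFF && !is.na(ep_open)) {
      eps <- rbind(eps, c(ep_open, ann$times[j] + 1))
      ep_open <- NA_real_
    }
  }
  if (!is.na(ep_open)) eps <- rbind(eps, c(ep_open, Inf))
  if (is.null(eps)) eps <- matrix(numeric(0), ncol = 2)
  reference_beats(beat_times, labels, eps)
}

.write_mit_annotations <- function(times, codes, path) {
  # times are 1-based sample indices; file stores 0-based cumulative intervals
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0
  for (j in seq_along(times)) {
    delta <- (times[j] - 1) - prev
    prev <- times[j] - 1
    if (delta > 1023 || delta < 0) {
      writeBin(as.raw(c(0L, 59L * 4L)), con)             # SKIP word
      skip <- delta
      if (skip < 0) skip <- skip + 2^32
      w1 <- skip %/% 65536
      w2 <- skip %% 65536
      writeBin(as.raw(c(w1 %% 256, w1 %/% 256, w2 %% 256, w2 %/% 256)), con)
      delta <- 0
    }
    writeBin(as.raw(c(delta %% 256, codes[j] * 4L + delta %/% 256)), con)
  }
  writeBin(as.raw(c(0L, 0L)), con)                        # EOF
  invisible(path)
}

# ---- VF exclusion ----------------------------------------------------------

#' Exclude beats inside ventricular flutter/fibrillation episodes
#'
#' Removes every beat whose time falls inside any VF episode; the episodes
#' themselves are retained so detections can be filtered symmetrically.
#' Idempotent.
#'
#' @param beats a [reference_beats()].
#' @return A [reference_beats()] without the in-episode beats.
#' @export
exclude_vf <- function(beats) {
  stopifnot(inherits(beats, "reference_beats"))
  if (!nrow(beats$vf_episodes) || !length(beats$times)) return(beats)
  inside <- rep(FALSE, length(beats$times))
  for (e in seq_len(nrow(beats$vf_episodes))) {
    inside <- inside | (beats$times >= beats$vf_episodes[e, 1] &
                        beats$times < beats$vf_episodes[e, 2])
  }
  reference_beats(beats$times[!inside], beats$labels[!inside],
                  beats$vf_episodes)
}

# ---- detection output ------------------------------------------------------

#' Write detected beats to CSV or a WFDB-style annotation file
#'
#' The CSV dialect is comma-separated with a dot decimal mark and a mandatory
#' header row: columns `r_sample`, `r_time_s`, `q_sample`, `s_sample`,
#' `template`.  The WFDB dialect writes an MIT-format annotation stream with
#' beat code `N` at each R sample.
#'
#' @param x a [detect_beats()] result, or a beats data frame with columns
#'   `r`, `r_time`, `q`, `s`, `template` sorted by R time.
#' @param dest output file path.
#' @param format `"csv"` or `"wfdb"`.
#' @return `dest`, invisibly.
#' @export
write_detections <- function(x, dest, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  beats <- if (inherits(x, "detection_run")) x$beats else x
  if (nrow(beats) && is.unsorted(beats$r_time))
    stop("beats must be sorted by R time")
  if (format == "csv") {
    df <- data.frame(r_sample = beats$r, r_time_s = beats$r_time,
                     q_sample = beats$q, s_sample = beats$s,
                     template = beats$template)
    utils::write.csv(df, dest, row.names = FALSE, quote = FALSE)
  } else {
    .write_mit_annotations(beats$r, rep(1L, nrow(beats)), dest)
  }
  invisible(dest)
}

#' Read back a detections CSV
#'
#' @param path a CSV written by [write_detections()].
#' @return A data frame with columns `r`, `r_time`, `q`, `s`, `template`.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, colClasses = c(template = "character"))
  data.frame(r = df$r_sample, r_time = df$r_time_s, q = df$q_sample,
             s = df$s_sample, template = df$template)
}
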