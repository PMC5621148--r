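# Independent oracles and fixture builders used across the suite.

# brute-force double-loop mask convolution (independent of apply_mask)
brute_mask <- function(x, k) {
  m <- c(rep(-1, k), 2 * k, rep(-1, k))
  n <- length(x)
  out <- rep(0, n)
  for (i in (k + 1):(n - k)) {
    acc <- 0
    for (j in -k:k) acc <- acc + m[k + j + 1] * x[i + j]
    out[i] <- acc
  }
  out
}

# optimal beat-pairing count by dynamic programming over the (sorted)
# reference x detection grid; for sorted lists an optimal matching can be
# taken non-crossing, so this equals the maximum bipartite matching size
oracle_max_pairs <- function(reference, detected, tol) {
  nr <- length(reference)
  nd <- length(detected)
  f <- matrix(0L, nr + 1L, nd + 1L)
  for (i in seq_len(nr)) {
    for (j in seq_len(nd)) {
      best <- max(f[i, j + 1L], f[i + 1L, j])
      if (abs(reference[i] - detected[j]) < tol)
        best <- max(best, f[i, j] + 1L)
      f[i + 1L, j + 1L] <- best
    }
  }
  f[nr + 1L, nd + 1L]
}

# random physiological matching instance: reference beats at least 0.4 s
# apart (so each detection can match at most one reference), detections are
# jittered copies with random drops plus spurious extras
random_match_instance <- function(n_max = 20, tol = 0.15) {
  n <- sample.int(n_max, 1)
  ref <- cumsum(stats::runif(n, 0.4, 1.5))
  keep <- stats::runif(n) > 0.15
  det <- ref[keep] + stats::runif(sum(keep), -1.2 * tol, 1.2 * tol)
  n_fp <- stats::rpois(1, 1)
  if (n_fp > 0) det <- c(det, stats::runif(n_fp, 0, max(ref) + 1))
  list(reference = ref, detected = sort(det))
}

# wrap a bare values vector as a transformed window (full range valid),
# for driving the fiducial state machine directly
make_tw <- function(values, fs = 360, global_start = 1L, k = 1L) {
  n <- length(values)
  structure(list(values = values, k = k, valid_lo = k + 1L,
                 valid_hi = n - k, fs = fs,
                 global_start = as.integer(global_start),
                 scale = 1, rejected = FALSE),
            class = "transformed_window")
}

# plant narrow Gaussian bumps at given times/amplitudes on a zero baseline
planted_values <- function(n, fs, centers_s, amps, sigma_s = 0.008) {
  t <- (seq_len(n) - 1) / fs
  v <- rep(0, n)
  for (i in seq_along(centers_s))
    v <- v + amps[i] * exp(-(t - centers_s[i])^2 / (2 * sigma_s^2))
  v
}

# independent rule-table trace of the four-case state machine, operating on
# the *planted* extremum configuration (positions/values known by
# construction, onsets from the closed-form Gaussian threshold crossing)
oracle_first_fiducial <- function(centers_s, amps, fs,
                                  pos_thr = 0.22, neg_thr = -0.2,
                                  high_thr = 0.52, range_s = 0.3,
                                  sigma_s = 0.008) {
  ord <- order(centers_s)
  centers_s <- centers_s[ord]
  amps <- amps[ord]
  is_crest <- amps > pos_thr
  is_trough <- amps < neg_thr
  onset <- centers_s - sigma_s * sqrt(2 * log(pmax(amps, pos_thr + 1e-12) / pos_thr))
  crest_pos <- centers_s[is_crest]
  crest_amp <- amps[is_crest]
  crest_onset <- onset[is_crest]
  trough_pos <- centers_s[is_trough]
  if (!length(crest_pos)) return(NULL)
  start <- crest_onset[1]
  repeat {
    inc <- crest_pos >= start & crest_pos < start + range_s
    int <- trough_pos >= start & trough_pos < start + range_s
    nc <- sum(inc)
    nt <- sum(int)
    cp <- crest_pos[inc]
    ca <- crest_amp[inc]
    tp <- trough_pos[int]
    if (nc == 1 && nt == 1)
      return(list(time = cp, case = "I"))
    if (nc == 2 && nt == 1 && tp > cp[1] && tp < cp[2])
      return(list(time = tp, case = "II"))
    if (nc == 1 && nt == 0 && ca > high_thr)
      return(list(time = cp, case = "III"))
    nxt <- crest_onset[crest_pos > cp[1]]
    if (!length(nxt)) return(NULL)
    start <- nxt[1]
  }
}
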