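cfg <- detector_config()

test_that("find_extrema reduces threshold runs to single crests/troughs", {
  v <- planted_values(720, 360, centers_s = c(0.5, 0.6), amps = c(0.8, -0.5))
  ex <- find_extrema(make_tw(v), cfg)
  expect_equal(nrow(ex), 2)
  expect_equal(ex$polarity, c("crest", "trough"))
  expect_equal(ex$index, c(181, 217))  # 0.5 s and 0.6 s at 360 Hz, 1-based
  expect_equal(ex$value[1], max(v))
  expect_equal(ex$value[2], min(v))
})

test_that("find_extrema returns nothing between the thresholds", {
  v <- planted_values(720, 360, centers_s = c(0.5, 0.9), amps = c(0.2, -0.18))
  expect_equal(nrow(find_extrema(make_tw(v), cfg)), 0)
})

test_that("a supra-threshold plateau yields one crest at its first index", {
  v <- rep(0, 400)
  v[100:110] <- 0.8            # flat plateau
  ex <- find_extrema(make_tw(v), cfg)
  expect_equal(nrow(ex), 1)
  expect_equal(ex$index, 100)
})

test_that("activation gate requires a strictly larger than 0.5 mV range", {
  w_flat <- ecg_window(rep(0, 720), fs = 360)
  expect_false(activation_check(w_flat, cfg))
  w_ok <- ecg_window(c(rep(-0.3, 360), rep(0.3, 360)), fs = 360)
  expect_true(activation_check(w_ok, cfg))
  w_edge <- ecg_window(c(rep(-0.25, 360), rep(0.25, 360)), fs = 360)
  expect_false(activation_check(w_edge, cfg))  # exactly 0.5 mV is not enough
})

test_that("state machine resolves the four constructed cases", {
  fs <- 360
  # Case I: one crest then one trough in range
  v <- planted_values(720, fs, c(0.5, 0.56), c(0.45, -0.5))
  f <- detect_fiducials(make_tw(v), cfg)
  expect_equal(f$case_label[1], "I")
  expect_equal(f$index[1], 181)

  # Case II: crest - trough - crest
  v <- planted_values(720, fs, c(0.45, 0.5, 0.55), c(0.45, -0.8, 0.4))
  f <- detect_fiducials(make_tw(v), cfg)
  expect_equal(f$case_label[1], "II")
  expect_equal(f$index[1], 181)    # the trough
  expect_equal(f$source[1], "trough")

  # Case III: a lone tall crest
  v <- planted_values(720, fs, 0.5, 0.6)
  f <- detect_fiducials(make_tw(v), cfg)
  expect_equal(f$case_label[1], "III")
  expect_equal(f$index[1], 181)

  # Case IV with no further crest: a lone low crest yields nothing
  v <- planted_values(720, fs, 0.5, 0.4)
  expect_equal(nrow(detect_fiducials(make_tw(v), cfg)), 0)

  # Case IV restarts: a cluttered opening (3 crests, 3 troughs) restarts at
  # the second crest (2 crests, 2 troughs -> Case IV again), then at the
  # third, which finally forms Case I with its trailing trough
  v <- planted_values(720, fs,
                      c(0.40, 0.44, 0.48, 0.52, 0.56, 0.60),
                      c(0.30, -0.4, 0.30, -0.4, 0.30, -0.4))
  f <- detect_fiducials(make_tw(v), cfg)
  expect_equal(f$case_label, "I")
  expect_equal(f$index, round(0.56 * fs) + 1L)
})

test_that("state machine agrees with a rule-table oracle on random layouts", {
  set.seed(101)
  fs <- 360
  n_checked <- 0
  for (rep in 1:200) {
    n_ext <- sample(1:4, 1)
    # first extremum is always a crest; spacing >= 0.045 s keeps runs apart
    centers <- 0.3 + cumsum(c(0, runif(n_ext - 1, 0.045, 0.09)))
    amps <- c(runif(1, 0.25, 1),
              runif(n_ext - 1, -1, 1))
    # push mid-range amplitudes out of the dead zone so every planted bump
    # is an extremum
    amps[amps >= 0 & amps < 0.25] <- amps[amps >= 0 & amps < 0.25] + 0.3
    amps[amps < 0 & amps > -0.25] <- amps[amps < 0 & amps > -0.25] - 0.3
    # keep crest amplitudes clear of the 0.52 lone-crest threshold, where
    # the sampled peak (up to ~1.5% under the analytic amplitude) and the
    # planted amplitude could fall on different sides
    amps[amps > 0.50 & amps < 0.54] <- 0.56
    v <- planted_values(720, fs, centers, amps)
    got <- detect_fiducials(make_tw(v), cfg)
    want <- oracle_first_fiducial(centers, amps, fs)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_gt(nrow(got), 0)
      expect_equal(got$case_label[1], want$case)
      expect_equal(got$index[1], round(want$time * fs) + 1L)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)  # the property must actually exercise fiducials
})

test_that("clean sinus rhythm yields exactly one fiducial per beat", {
  for (bpm in c(60, 120, 180)) {
    rec <- synth_ecg(20, bpm)
    run <- detect_beats(rec$signal)
    m <- match_beats(run$beats$r_time, (rec$truth_r - 1) / 360, 0.15)
    expect_equal(nrow(run$beats), 20)
    expect_length(m$unmatched_ref, 0)
    expect_length(m$unmatched_det, 0)
  }
})

test_that("fiducial output is strictly increasing and case II/III spaced", {
  rec <- synth_ecg(20, 150, kinds = "d")
  band <- bandpass_filter(rec$signal$samples, 360, 0.5, 17)
  qrs_n <- round(0.12 * 360)
  for (w in refresh_windows(band, fs = 360)) {
    tw <- transform_window(w, 1)
    if (tw$rejected) next
    f <- detect_fiducials(tw, cfg)
    if (nrow(f) < 2) next
    expect_true(all(diff(f$index) > 0))
    ii <- which(f$case_label %in% c("II", "III"))
    ii <- ii[ii < nrow(f)]
    if (length(ii))
      expect_true(all(f$index[ii + 1] - f$index[ii] >= qrs_n))
  }
})

test_that("fiducial detection is deterministic", {
  rec <- synth_ecg(10, 75, kinds = "b")
  r1 <- detect_beats(rec$signal)
  r2 <- detect_beats(rec$signal)
  expect_identical(r1$beats, r2$beats)
})
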