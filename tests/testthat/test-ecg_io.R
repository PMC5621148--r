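# hand-rolled encoders, independent of the package's readers

pack_212 <- function(values) {
  if (length(values) %% 2 == 1) values <- c(values, 0L)
  vv <- ifelse(values < 0, values + 4096L, values)
  out <- raw(0)
  for (i in seq(1, length(vv), by = 2)) {
    v1 <- vv[i]; v2 <- vv[i + 1]
    out <- c(out, as.raw(c(v1 %% 256, (v1 %/% 256) + 16 * (v2 %/% 256),
                           v2 %% 256)))
  }
  out
}

ann_word <- function(code, interval) {
  as.raw(c(interval %% 256, code * 4 + interval %/% 256))
}

write_wfdb_fixture <- function(dir, name = "t1", two_leads = TRUE) {
  mlii_adc <- c(0L, 200L, -200L, 400L, 100L) + 1024L
  v5_adc <- c(0L, 20L, 40L, 60L, 80L) + 1024L
  if (two_leads) {
    hea <- c(sprintf("%s 2 360 5", name),
             sprintf("%s.dat 212 200 11 1024 0 0 0 MLII", name),
             sprintf("%s.dat 212 200 11 1024 0 0 0 V5", name))
    inter <- as.integer(rbind(mlii_adc, v5_adc))
  } else {
    hea <- c(sprintf("%s 1 360 5", name),
             sprintf("%s.dat 212 200 11 1024 0 0 0 V5", name))
    inter <- v5_adc
  }
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  writeBin(pack_212(inter), file.path(dir, paste0(name, ".dat")))
  file.path(dir, name)
}

test_that("WFDB 212 records decode to mV with the preferred lead", {
  dir <- withr::local_tempdir()
  base <- write_wfdb_fixture(dir)
  rec <- read_record(base, c("MLII", "V5"))
  expect_s3_class(rec, "signal_record")
  expect_equal(rec$fs, 360)
  expect_equal(rec$lead_name, "MLII")
  expect_equal(rec$samples, c(0, 1, -1, 2, 0.5))   # (adc - 1024) / 200
  expect_equal(rec$length, 5)                      # header-declared count

  rec2 <- read_record(base, c("V5"))
  expect_equal(rec2$lead_name, "V5")
  expect_equal(rec2$samples, c(0, 0.1, 0.2, 0.3, 0.4))
})

test_that("lead preference falls back and errors when nothing matches", {
  dir <- withr::local_tempdir()
  base <- write_wfdb_fixture(dir, name = "v5only", two_leads = FALSE)
  rec <- read_record(base, c("MLII", "V5"))
  expect_equal(rec$lead_name, "V5")
  expect_error(read_record(base, c("MLII")), "preferred")
  expect_error(read_record(file.path(dir, "absent")), "missing")
})

test_that("CSV records pass through with inferred sampling rate", {
  f <- withr::local_tempfile(fileext = ".csv")
  n <- 720
  df <- data.frame(t = (0:(n - 1)) / 360, mv = sin(2 * pi * (0:(n - 1)) / 360))
  write.csv(df, f, row.names = FALSE)
  rec <- read_record(f)
  expect_equal(rec$lead_name, "CSV")
  expect_equal(rec$fs, 360, tolerance = 1e-9)
  expect_equal(rec$samples, df$mv)
})

test_that("MIT annotation streams parse beats, skips and flutter markers", {
  f <- withr::local_tempfile(fileext = ".atr")
  stream <- c(
    ann_word(1, 10),              # N at 10
    ann_word(5, 390),             # V at 400
    ann_word(61, 1),              # SUB attribute: no time advance
    as.raw(c(3, 252)),            # AUX, 3 payload bytes (+1 pad)
    charToRaw("(N"), as.raw(c(0, 0)),
    as.raw(c(0, 59 * 4)),         # SKIP word ...
    as.raw(c(0, 0, 1600 %% 256, 1600 %/% 256)),  # ... +1600 samples
    ann_word(32, 0),              # flutter onset at 2000
    ann_word(1, 100),             # N at 2100 (inside the episode)
    ann_word(33, 100),            # flutter end at 2200
    ann_word(1, 300),             # N at 2500
    as.raw(c(0, 0))               # EOF
  )
  writeBin(stream, f)
  ref <- read_annotations(f)
  expect_equal(ref$times, c(11, 401, 2101, 2501))  # 1-based
  expect_equal(ref$labels, c("N", "V", "N", "N"))
  expect_equal(nrow(ref$vf_episodes), 1)
  expect_equal(unname(ref$vf_episodes[1, ]), c(2001, 2201))

  kept <- exclude_vf(ref)
  expect_equal(kept$times, c(11, 401, 2501))
})

test_that("an annotation stream with zero beats parses to empty", {
  f <- withr::local_tempfile(fileext = ".atr")
  writeBin(as.raw(c(0, 0)), f)
  ref <- read_annotations(f)
  expect_length(ref$times, 0)
  expect_length(ref$labels, 0)
})

test_that("flutter exclusion removes in-episode beats and is idempotent", {
  ref <- reference_beats(c(10, 50, 90), c("N", "N", "N"),
                         matrix(c(40, 60), ncol = 2))
  out <- exclude_vf(ref)
  expect_equal(out$times, c(10, 90))
  expect_equal(exclude_vf(out)$times, c(10, 90))   # idempotent
  expect_equal(nrow(out$vf_episodes), 1)           # episodes retained

  all_in <- reference_beats(c(45, 50), c("N", "N"),
                            matrix(c(40, 60), ncol = 2))
  expect_length(exclude_vf(all_in)$times, 0)

  none <- reference_beats(c(10, 50), c("N", "N"))
  expect_equal(exclude_vf(none)$times, c(10, 50))
})

test_that("detection CSV round-trips and uses seconds from sample 721", {
  f <- withr::local_tempfile(fileext = ".csv")
  fs <- 360
  beats <- data.frame(q = 711L, ra = 721L, r = 721L, s = 731L,
                      template = "a", case_label = "I", fiducial = 721L,
                      r_time = (721 - 1) / fs)
  write_detections(beats, f)
  back <- read_detections(f)
  expect_equal(back$r_time, 2.0)
  expect_equal(back$r, 721)

  # empty detections: header-only CSV
  write_detections(beats[0, ], f)
  expect_equal(nrow(read.csv(f)), 0)
  expect_equal(names(read.csv(f)),
               c("r_sample", "r_time_s", "q_sample", "s_sample", "template"))

  # 10-beat round trip preserves R samples exactly
  set.seed(2)
  r <- sort(sample(1:100000, 10))
  many <- data.frame(q = r - 10L, ra = r, r = r, s = r + 10L,
                     template = "a", case_label = "I", fiducial = r,
                     r_time = (r - 1) / fs)
  write_detections(many, f)
  expect_equal(read_detections(f)$r, r)
})

test_that("WFDB-dialect detections are readable as annotations", {
  f <- withr::local_tempfile(fileext = ".atr")
  fs <- 360
  r <- c(150L, 5000L, 5200L, 120000L)   # includes >1023-sample gaps
  beats <- data.frame(q = r - 10L, ra = r, r = r, s = r + 10L,
                      template = "a", case_label = "I", fiducial = r,
                      r_time = (r - 1) / fs)
  write_detections(beats, f, format = "wfdb")
  back <- read_annotations(f)
  expect_equal(back$times, as.numeric(r))
  expect_equal(back$labels, rep("N", 4))
})
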