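test_that("recording files parse, round-trip, and report defects", {
  dir <- withr::local_tempdir()
  # 3-sample toy file at 1 kHz radar rate
  toy <- file.path(dir, "toy.csv")
  writeLines(c("#subject_id=T1", "#rate_ecg=250", "#rate_i=1000",
               "#rate_q=1000", "channel,t,value",
               "i,0.000,1.5", "i,0.001,2.5", "i,0.002,3.5",
               "q,0.000,-1", "q,0.001,-2", "q,0.002,-3"), toy)
  rec <- read_recording(toy)
  expect_equal(rec$subject_id, "T1")
  expect_length(rec$i_ch$values, 3)
  expect_length(rec$q_ch$values, 3)
  expect_length(rec$ecg$values, 0)         # empty channel is legal
  expect_equal(rec$i_ch$rate, 1000)
  expect_equal(rec$ecg$rate, 250)          # distinct declared rates preserved

  # duplicated timestamp -> parse error naming the line
  bad <- file.path(dir, "bad.csv")
  writeLines(c("#rate_ecg=250", "#rate_i=1000", "#rate_q=1000",
               "channel,t,value",
               "i,0.000,1", "i,0.001,2", "i,0.001,3"), bad)
  expect_error(read_recording(bad), "non-monotone.*line 7")

  # missing column
  nocol <- file.path(dir, "nocol.csv")
  writeLines(c("#rate_ecg=250", "#rate_i=1000", "#rate_q=1000",
               "channel,t", "i,0.0"), nocol)
  expect_error(read_recording(nocol), "missing column")

  # declared rate inconsistent with timestamps
  badrate <- file.path(dir, "badrate.csv")
  writeLines(c("#rate_ecg=250", "#rate_i=1000", "#rate_q=1000",
               "channel,t,value",
               "i,0.00,1", "i,0.01,2", "i,0.02,3"), badrate)
  expect_error(read_recording(badrate), "rate mismatch")

  # round-trip of a 1 s simulated recording: identical counts, values to 1e-9
  rec1 <- generate_cohort(1, 1, seed = 2)[[1]]
  p <- file.path(dir, "rt.csv")
  write_recording(rec1, p)
  back <- read_recording(p)
  for (ch in c("ecg", "i_ch", "q_ch")) {
    expect_length(back[[ch]]$values, length(rec1[[ch]]$values))
    expect_close(back[[ch]]$values, rec1[[ch]]$values,
                 tol = 1e-9 * max(1, max(abs(rec1[[ch]]$values))))
  }

  # empty channels -> valid headers-only file that reads back
  empty <- subject_recording("E", time_series(numeric(0), 250),
                             time_series(numeric(0), 1000),
                             time_series(numeric(0), 1000))
  pe <- file.path(dir, "empty.csv")
  write_recording(empty, pe)
  back_e <- read_recording(pe)
  expect_length(back_e$i_ch$values, 0)
})

test_that("a longer cohort member survives the file round-trip", {
  dir <- withr::local_tempdir()
  rec <- generate_cohort(1, 20, seed = 9)[[1]]
  write_recording(rec, file.path(dir, "s.csv"))
  write_beats(rec$truth_beats, file.path(dir, "s.beats.txt"))
  back <- read_recording(file.path(dir, "s.csv"))
  expect_close(back$i_ch$values, rec$i_ch$values, tol = 1e-9)
  expect_close(back$q_ch$values, rec$q_ch$values, tol = 1e-9)
  expect_close(back$ecg$values, rec$ecg$values, tol = 1e-9)
  beats <- read_beats(file.path(dir, "s.beats.txt"))
  expect_close(beats$times, rec$truth_beats$times, tol = 1e-12)
})

test_that("decimation preserves DC, sample counts, and suppresses aliases", {
  # DC invariance
  const <- time_series(rep(3.7, 1000), 1000)
  d <- decimate(const, 100)
  expect_close(d$values, rep(3.7, 100), tol = 1e-6)

  # 2000 samples at 1 kHz -> 200 at 100 Hz (1 s of 100 Hz data = 100 samples)
  x <- time_series(sin(2 * pi * 2 * (0:1999) / 1000), 1000)
  expect_length(decimate(x, 100)$values, 200)

  # non-integer factor refused
  expect_error(decimate(x, 300), "integer multiple")

  # alias suppression: 1 Hz retained, 300 Hz (aliasing to 30 Hz) down >= 40 dB
  t <- (0:9999) / 1000
  s <- time_series(sin(2 * pi * 1 * t) + sin(2 * pi * 300 * t), 1000)
  out <- decimate(s, 100)$values
  sp <- abs(stats::fft(out))                        # bins: (k-1)/10 Hz over 10 s
  amp_1hz <- sp[11]                                 # 1 Hz bin
  amp_alias <- max(sp[291:311])                     # 29-31 Hz alias band
  expect_gt(20 * log10(amp_1hz / amp_alias), 40)
  expect_gt(amp_1hz, 0.8 * length(out) / 2)         # 1 Hz essentially intact

  # composition: two-stage decimation agrees with direct within filter tol
  y <- time_series(sin(2 * pi * 3 * t) + 0.3 * cos(2 * pi * 7 * t), 1000)
  two <- decimate(decimate(y, 500), 100)$values
  one <- decimate(y, 100)$values
  expect_close(two[10:990], one[10:990], tol = 5e-3)

  # empty input propagates
  expect_length(decimate(time_series(numeric(0), 1000), 100)$values, 0)
})

test_that("alignment trims to the common clock and is idempotent", {
  v <- function(n, rate, t0) time_series(seq_len(n), rate, t0)
  rec <- subject_recording("A",
                           ecg = v(2500, 250, 0.50),   # ECG starts 0.5 s late
                           i_ch = v(10500, 1000, 0),
                           q_ch = v(10500, 1000, 0))
  al <- align_recording(rec)
  expect_equal(al$i_ch$values[1], 501)      # 500 samples trimmed at 1 kHz
  expect_equal(al$q_ch$values[1], 501)
  expect_equal(al$ecg$values[1], 1)
  spans <- c(length(al$ecg$values) / 250, length(al$i_ch$values) / 1000,
             length(al$q_ch$values) / 1000)
  expect_lt(diff(range(spans)), 1 / 250 + 1e-9)

  # idempotent
  al2 <- align_recording(al)
  expect_identical(al2$i_ch$values, al$i_ch$values)
  expect_identical(al2$ecg$values, al$ecg$values)
  expect_identical(al2$ecg$t0, al$ecg$t0)

  # already-aligned channels unchanged
  rec0 <- subject_recording("B", v(1000, 250, 0), v(4000, 1000, 0),
                            v(4000, 1000, 0))
  al0 <- align_recording(rec0)
  expect_identical(al0$i_ch$values, rec0$i_ch$values)

  # zero overlap -> error
  recx <- subject_recording("C", v(250, 250, 100), v(1000, 1000, 0),
                            v(1000, 1000, 0))
  expect_error(align_recording(recx), "overlap")
})

test_that("cropping is exact, half-open, and carries truth beats", {
  rec <- generate_cohort(1, 30, seed = 4)[[1]]
  cr <- crop_recording(rec, 5, 25)
  expect_length(cr$i_ch$values, 20000)
  expect_length(cr$ecg$values, 5000)
  # byte-identical sub-sequence (no filtering)
  expect_identical(cr$i_ch$values, rec$i_ch$values[5001:25000])
  expect_equal(cr$i_ch$t0, 5)

  # crop to full span is the identity
  full <- crop_recording(rec, 0, 30)
  expect_identical(full$q_ch$values, rec$q_ch$values)

  # boundary: a truth beat just before the window is dropped
  rec$truth_beats <- beat_train(c(4.9, 5.1, 10))
  cr2 <- crop_recording(rec, 5, 25)
  expect_equal(cr2$truth_beats$times, c(5.1, 10))

  # out-of-span window errors
  expect_error(crop_recording(rec, -1, 10), "outside")
  expect_error(crop_recording(rec, 10, 40), "outside")
  expect_error(crop_recording(rec, 10, 10), "start < stop")
})
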