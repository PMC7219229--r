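test_that("beat trains follow the requested rate, jitter and truncation", {
  # jitter-free 60 bpm: events exactly 1.0 s apart
  b <- generate_beat_train(steady_vitals(60), 10, seed = 1)
  expect_close(diff(b$times), rep(1, length(b$times) - 1), tol = 1e-12)

  # 120 bpm -> mean RR 0.5 s
  b2 <- generate_beat_train(vital_model(mean_hr = 120, hrv_sd = 0.01), 300,
                            seed = 2)
  expect_lt(abs(mean(diff(b2$times)) - 0.5), 0.01)

  # 200 s at 75 bpm: count within 3 sigma of 250, reproducible per seed
  m <- vital_model(mean_hr = 75, hrv_sd = 0.04)
  b3 <- generate_beat_train(m, 200, seed = 3)
  # count ~ duration / mean RR; sd of count ~ sqrt(n) * hrv_sd / mean RR
  expect_lt(abs(length(b3$times) - 250), 3 * sqrt(250) * 0.04 / 0.8 + 3)
  b3b <- generate_beat_train(m, 200, seed = 3)
  expect_identical(b3$times, b3b$times)

  # RR truncation bounds hold for every seed (property)
  mj <- vital_model(mean_hr = 70, hrv_sd = 0.5) # absurd jitter to force clamps
  for (s in 1:20) {
    rr <- diff(generate_beat_train(mj, 60, seed = s)$times)
    expect_true(all(rr >= 0.5 - 1e-12 & rr <= 1.5 + 1e-12))
  }
})

test_that("chest displacement places each beat inside its target window", {
  m <- vital_model()
  # no beats, breathing off -> all-zero trace
  m0 <- m; m0$breath_amp <- 0; m0$beat_amp <- 1e-4
  x0 <- chest_displacement(beat_train(numeric(0)), m0, 1000, 5, seed = 1)
  expect_close(x0$values, numeric(5000), tol = 0)

  # single beat, breathing off -> peak displacement equals beat_amp
  x1 <- chest_displacement(beat_train(2), m0, 1000, 5, seed = 2)
  expect_lt(abs(max(abs(x1$values)) - m0$beat_amp), 1e-3 * m0$beat_amp)

  # every per-beat contribution confined to [t_k + 0.2, t_k + 0.6) for all
  # electro-mechanical delays in the default range (support check)
  beats <- generate_beat_train(steady_vitals(75), 10, seed = 3)
  for (s in 1:5) {
    x <- chest_displacement(beats, m0, 1000, 10, seed = s)
    t <- ts_times(x)
    outside <- rep(TRUE, length(t))
    for (tk in beats$times) outside[t >= tk + 0.2 & t < tk + 0.6] <- FALSE
    expect_lt(max(abs(x$values[outside])), 1e-9)
  }
})

test_that("quadrature synthesis evaluates the baseband model exactly", {
  p <- ideal_params(theta0 = 0.7)
  # static target: constant channels at the operating point
  x0 <- time_series(numeric(100), 1000)
  iq <- synthesize_iq(x0, p, seed = 1)
  expect_close(iq$i$values, rep(cos(0.7), 100), tol = 1e-12)
  expect_close(iq$q$values, rep(sin(0.7), 100), tol = 1e-12)

  # with imbalance and offsets: I = A_I cos(theta0)+DC_I etc.
  p2 <- radar_params(theta0 = 0.3, A_I = 1.2, A_Q = 0.8, DC_I = 0.4,
                     DC_Q = -0.2, dphi = 0.1, noise_sd = 0)
  iq2 <- synthesize_iq(x0, p2, seed = 1)
  expect_close(iq2$i$values[1], 1.2 * cos(0.3) + 0.4, tol = 1e-12)
  expect_close(iq2$q$values[1], 0.8 * sin(0.3 + 0.1) - 0.2, tol = 1e-12)

  # a lambda/8 step advances the phase by pi/2: I goes A_I -> 0, Q 0 -> A_Q
  p3 <- ideal_params(theta0 = 0)
  xs <- time_series(c(0, p3$wavelength / 8), 1000)
  iq3 <- synthesize_iq(xs, p3, seed = 1)
  expect_close(iq3$i$values, c(1, 0), tol = 1e-12)
  expect_close(iq3$q$values, c(0, 1), tol = 1e-12)

  # 24 GHz carrier: lambda ~ 12.5 mm, so 0.3 mm spans ~0.3 rad of phase
  expect_lt(abs(p$wavelength - 0.0125), 1e-4)
  expect_lt(abs(4 * pi * 3e-4 / p$wavelength - 0.302), 0.005)

  # phase-exactness: I^2 + Q^2 constant when noise and offsets are zero
  xr <- time_series(1e-3 * sin(2 * pi * 0.3 * (0:999) / 1000), 1000)
  iq4 <- synthesize_iq(xr, ideal_params(), seed = 2)
  expect_close(iq4$i$values^2 + iq4$q$values^2, rep(1, 1000), tol = 1e-12)
})

test_that("synthetic ECG anchors the R apex and keeps other waves small", {
  # no beats: noise-only, well below R amplitude / 5
  e0 <- synthesize_ecg(beat_train(numeric(0)), 250, 10, seed = 1)
  expect_lt(max(abs(e0$values)), 1 / 5)

  # one beat at 1.0 s, 250 Hz -> global maximum exactly at sample index 250
  e1 <- synthesize_ecg(beat_train(1.0), 250, 3, seed = 2)
  expect_equal(which.max(e1$values) - 1L, 250L)

  # 60 bpm over 60 s -> 60 local maxima above half the R amplitude
  b <- generate_beat_train(steady_vitals(60), 60, seed = 3)
  e2 <- synthesize_ecg(b, 250, 60, seed = 3)
  v <- e2$values
  peaks <- which(v[2:(length(v) - 1)] > v[1:(length(v) - 2)] &
                 v[2:(length(v) - 1)] > v[3:length(v)]) + 1L
  expect_equal(sum(v[peaks] > 0.5), length(b$times))
})

test_that("cohort generation is reproducible and physiologically bounded", {
  co <- generate_cohort(3, 20, seed = 5)
  expect_length(co, 3)
  for (rec in co) {
    expect_length(rec$i_ch$values, 20 * 1000)
    expect_length(rec$q_ch$values, 20 * 1000)
    expect_length(rec$ecg$values, 20 * 250)
    # truth beat count inside the 40-120 bpm band for the duration
    expect_gte(length(rec$truth_beats$times), 20 * 40 / 60 - 1)
    expect_lte(length(rec$truth_beats$times), 20 * 120 / 60 + 1)
    expect_true(all(rec$truth_beats$times >= 0 &
                    rec$truth_beats$times < 20))
  }
  # same seed twice -> identical recordings
  co2 <- generate_cohort(3, 20, seed = 5)
  expect_identical(co[[2]]$i_ch$values, co2[[2]]$i_ch$values)
  expect_identical(co[[3]]$ecg$values, co2[[3]]$ecg$values)
  expect_identical(co[[1]]$truth_beats$times, co2[[1]]$truth_beats$times)
  # subjects differ from each other
  expect_false(identical(co[[1]]$i_ch$values, co[[2]]$i_ch$values))
})

test_that("cohort save/load round-trips recordings and truth beats", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort(2, 10)
  save_cohort(co, dir, config = list(note = "fixture"))
  back <- load_cohort(dir)
  expect_length(back, 2)
  expect_close(back[[1]]$i_ch$values, co[[1]]$i_ch$values, tol = 1e-9)
  expect_close(back[[2]]$truth_beats$times, co[[2]]$truth_beats$times,
               tol = 1e-12)
  expect_true(file.exists(file.path(dir, "cohort_config.yaml")))
})
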