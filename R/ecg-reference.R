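# ECG-derived training target: Pan-Tompkins R-peak detection followed by the
# binarized target (a fixed-width pulse at a fixed delay after each R wave)
# synthesized directly at the common working rate.

#' Detect ECG R peaks with the Pan-Tompkins algorithm
#'
#' Classic stage chain: ~5-15 Hz band-pass, five-point derivative, squaring,
#' 150 ms moving-window integration, dual adaptive signal/noise thresholds
#' with a 200 ms refractory period and search-back at 1.66x the running RR
#' average. The band-pass and integration stages are applied zero-phase /
#' centred so integrated peaks stay aligned with the QRS; each detection is
#' then refined to the R apex on the original ECG within +/-40 ms.
#'
#' @param ecg a [time_series()] ECG at its native rate (>= 200 Hz); no
#'   resampling is performed.
#' @return a [beat_train()] of R-apex times, strictly increasing.
#' @export
pan_tompkins <- function(ecg) {
  stopifnot(inherits(ecg, "radar_ts"))
  fs <- ecg$rate
  if (fs < 200) stop("pan_tompkins requires an ECG rate of at least 200 Hz")
  v <- ecg$values
  n <- length(v)
  if (n < 2 * fs) stop("pan_tompkins requires at least 2 s of ECG")
  if (max(v) - min(v) < 1e-12) return(beat_train(numeric(0)))

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- filtfilt_padded(bf, v)
  # five-point derivative, centred (zero-phase)
  der <- stats::filter(bp, c(-2, -1, 0, 1, 2) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w <- max(3L, as.integer(round(0.15 * fs)))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # strict local maxima of the integrated signal, thinned so that no two
  # fiducial candidates are closer than the 200 ms refractory period (the
  # larger peak wins) -- P/T bumps adjacent to a QRS never shadow it
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (!length(cand)) return(beat_train(numeric(0)))
  refractory <- 0.2 * fs
  kept <- integer(0)
  for (p in cand[order(-mwi[cand], cand)]) {
    if (!length(kept) || all(abs(kept - p) >= refractory)) kept <- c(kept, p)
  }
  cand <- sort(kept)
  init <- seq_len(min(n, as.integer(2 * fs)))
  spki <- 0.25 * max(mwi[init])
  npki <- 0.5 * mean(mwi[init])
  thr1 <- function() npki + 0.25 * (spki - npki)

  accepted <- integer(0)
  rr_hist <- numeric(0)
  last_qrs <- -Inf
  for (p in cand) {
    if (p - last_qrs < refractory) next
    # search-back: long gap since the last beat -> revisit skipped candidates
    # with the lower threshold
    if (length(rr_hist) >= 2 && is.finite(last_qrs)) {
      rr_avg <- mean(utils::tail(rr_hist, 8))
      if ((p - last_qrs) > 1.66 * rr_avg) {
        gap <- cand[cand > last_qrs + refractory & cand < p - refractory]
        gap <- gap[mwi[gap] > 0.5 * thr1()]
        if (length(gap)) {
          gb <- gap[which.max(mwi[gap])]
          spki <- 0.25 * mwi[gb] + 0.75 * spki
          rr_hist <- c(rr_hist, gb - last_qrs)
          accepted <- c(accepted, gb)
          last_qrs <- gb
        }
      }
    }
    if (mwi[p] > thr1()) {
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (is.finite(last_qrs)) rr_hist <- c(rr_hist, p - last_qrs)
      accepted <- c(accepted, p)
      last_qrs <- p
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
  }
  accepted <- sort(accepted)
  if (!length(accepted)) return(beat_train(numeric(0)))

  # refine to the R apex on the raw ECG within +/-40 ms of the integrated peak
  half <- as.integer(round(0.04 * fs))
  apex <- vapply(accepted, function(p) {
    i0 <- max(1L, p - half); i1 <- min(n, p + half)
    i0 + which.max(v[i0:i1]) - 1L
  }, integer(1))
  apex <- sort(unique(apex))
  if (length(apex) > 1) apex <- apex[c(TRUE, diff(apex) > refractory / 2)]
  beat_train(ecg$t0 + (apex - 1) / fs)
}

#' Synthesize the binarized training target at the working rate
#'
#' The target is 1 at sample time `t` iff some beat `t_k` satisfies
#' `t in [t_k + delay, t_k + delay + width)`; overlapping pulses form their
#' union. The target is constructed directly on the output sample grid, which
#' is exactly equivalent to nearest-sample decimation of a high-rate binary
#' pulse train and keeps the values binary (an anti-alias filter would not).
#'
#' @param beats a [beat_train()] of reference R times.
#' @param rate target rate, Hz (100 by default).
#' @param span half-open time window `c(start, stop)` covered by the target, s.
#' @param delay pulse onset delay after each R wave, s (default 0.200).
#' @param width pulse width, s (default 0.400).
#' @return a [time_series()] with values in {0, 1}.
#' @export
#' @examples
#' bt <- binarize_targets(beat_train(1.0), rate = 100, span = c(0, 3))
#' sum(bt$values) # 40 samples covering [1.2, 1.6)
binarize_targets <- function(beats, rate = 100, span, delay = 0.2,
                             width = 0.4) {
  stopifnot(inherits(beats, "beat_train"), rate > 0, delay >= 0, width >= 0,
            length(span) == 2, span[1] < span[2])
  n <- as.integer(round((span[2] - span[1]) * rate))
  vals <- integer(n)
  for (tk in beats$times) {
    i0 <- as.integer(ceiling((tk + delay - span[1]) * rate - .eps))
    i1 <- as.integer(ceiling((tk + delay + width - span[1]) * rate - .eps)) - 1L
    i0 <- max(i0, 0L); i1 <- min(i1, n - 1L)
    if (i1 >= i0) vals[(i0:i1) + 1L] <- 1L
  }
  time_series(vals, rate, span[1])
}

#' Sweep the target delay/width grid and report detection rates
#'
#' For each (delay, width) pair, trains the smallest feed-forward topology
#' (one hidden layer of 10 units) on the supplied recordings and reports the
#' percentage of reference beats detected by the full chain. Used to confirm
#' the default 200 ms delay / 400 ms width; grid bounds must stay in [0, 1] s.
#'
#' @param recordings list of [subject_recording()] with ECG reference.
#' @param delays,widths numeric grids, s; duplicates are removed.
#' @param cfg a [train_config()] (reduce `max_epochs` for quick sweeps).
#' @param rate working rate, Hz.
#' @param memory input window length, s.
#' @param seed integer seed.
#' @return data.frame with columns `delay`, `width`, `detection_rate`.
#' @export
sweep_target_params <- function(recordings, delays, widths,
                                cfg = train_config(max_epochs = 30),
                                rate = 100, memory = 1.0, seed = 1) {
  stopifnot(length(recordings) >= 1)
  if (!length(delays) || !length(widths)) stop("empty delay/width grid")
  if (any(delays < 0 | delays > 1) || any(widths < 0 | widths > 1))
    stop("delay/width grid bounds must lie within [0, 1] s")
  grid <- unique(expand.grid(delay = delays, width = widths))
  prep <- lapply(recordings, prepare_subject, rate = rate)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    delay <- grid$delay[g]; width <- grid$width[g]
    ws <- combine_windows(lapply(prep, function(p) {
      target <- binarize_targets(p$ref_beats, rate, p$span, delay, width)
      build_windows(p$i, p$q, target, memory = memory)
    }), ids = vapply(prep, function(p) p$subject_id, ""))
    fit <- suppressWarnings(
      train_lm("FF 10 1", ws, replace_seed(cfg, derive_seed(seed, paste0("sweep", g)))))
    hits <- 0; total <- 0
    for (p in prep) {
      det <- detect_on_prepared(fit$model, p, amplitude = 0.1)
      m <- match_beats(det$beats, p$ref_beats, tol = 0.5)
      hits <- hits + sum(!is.na(m)); total <- total + length(p$ref_beats$times)
    }
    data.frame(delay = delay, width = width,
               detection_rate = 100 * hits / max(total, 1))
  })
  do.call(rbind, out)
}
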