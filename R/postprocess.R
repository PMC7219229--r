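# From the per-sample ANN probability stream to discrete heartbeat events:
# causal moving-average smoothing, prominence-constrained peak picking with a
# physiological minimum spacing, doubled-interval interpolation of missed
# beats, and empirical detection-amplitude calibration.

#' Causal moving-average smoothing
#'
#' Running mean over the last `width` outputs; the first `width - 1` samples
#' average over the history available so far. Causal (not centred) so that a
#' detection never depends on samples after the beat window. Length preserved.
#'
#' @param probs a [time_series()] of ANN outputs.
#' @param width filter width in samples (default 10).
#' @return a [time_series()] of the same length and rate.
#' @export
smooth_ma <- function(probs, width = 10L) {
  stopifnot(inherits(probs, "radar_ts"))
  if (!is.numeric(width) || length(width) != 1 || width < 1)
    stop("width must be a positive integer")
  width <- as.integer(width)
  v <- probs$values
  n <- length(v)
  if (n == 0 || width == 1L) return(probs)
  s <- cumsum(v)
  out <- numeric(n)
  head_n <- seq_len(min(width - 1L, n))
  out[head_n] <- s[head_n] / head_n
  if (n >= width) {
    k <- width:n
    out[k] <- (s[k] - c(0, s)[k - width + 1L]) / width
  }
  time_series(out, probs$rate, probs$t0)
}

# Prominence of a strict local maximum: height minus the higher of the two
# valley floors separating it from higher ground (or the series edge).
peak_prominences <- function(v, peaks) {
  vapply(peaks, function(i) {
    h <- v[i]
    left_min <- h
    j <- i - 1L
    while (j >= 1L && v[j] <= h) { left_min <- min(left_min, v[j]); j <- j - 1L }
    if (j < 1L) left_min <- min(left_min, min(v[1:i]))
    right_min <- h
    j <- i + 1L
    while (j <= length(v) && v[j] <= h) { right_min <- min(right_min, v[j]); j <- j + 1L }
    if (j > length(v)) right_min <- min(right_min, min(v[i:length(v)]))
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect beat events as prominent peaks of the smoothed probability trace
#'
#' Strict local maxima with prominence at least `amplitude` survive a greedy
#' minimum-distance suppression: no two surviving peaks are closer than
#' `60 / hr_range[2]` seconds (0.5 s at the 120 beats/min resting upper
#' bound), the higher peak winning (ties to the earlier peak).
#'
#' @param smoothed a [time_series()] (output of [smooth_ma()]).
#' @param amplitude prominence threshold (> 0), the "detection amplitude".
#' @param hr_range physiological heart-rate range, beats/min.
#' @return a [beat_train()] of peak-sample times.
#' @export
detect_peaks <- function(smoothed, amplitude, hr_range = c(40, 120)) {
  stopifnot(inherits(smoothed, "radar_ts"), amplitude > 0,
            length(hr_range) == 2, hr_range[1] > 0, hr_range[1] < hr_range[2])
  v <- smoothed$values
  n <- length(v)
  if (n < 3) return(beat_train(numeric(0)))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (!length(cand)) return(beat_train(numeric(0)))
  prom <- peak_prominences(v, cand)
  cand <- cand[prom >= amplitude]
  if (!length(cand)) return(beat_train(numeric(0)))
  min_gap <- (60 / hr_range[2]) * smoothed$rate
  ord <- cand[order(-v[cand], cand)] # height desc, ties -> earlier
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  beat_train(smoothed$t0 + (kept - 1) / smoothed$rate)
}

#' Interpolate beats missed inside doubled inter-pulse intervals
#'
#' Scans left to right keeping a running median of the last `history` accepted
#' IPIs (only IPIs inside the physiological band enter the history). When an
#' observed interval reaches twice the running median, one beat is inserted at
#' the arithmetic mean of the two flanking detections and flagged as
#' interpolated. Inserted half-intervals never enter the history; gaps beyond
#' three medians are left as dropouts (no recursive splitting).
#'
#' @param beats a [beat_train()] of detected events.
#' @param hr_range physiological heart-rate range, beats/min; sets the IPI
#'   band `[60/hr_max, 60/hr_min]` s.
#' @param history number of recent IPIs in the running median.
#' @return list of class `beat_detections`: `beats` (a [beat_train()]),
#'   `interpolated` (logical per beat), `amplitude_used`.
#' @export
interpolate_missed <- function(beats, hr_range = c(40, 120), history = 5L) {
  stopifnot(inherits(beats, "beat_train"), history >= 1)
  lo <- 60 / hr_range[2]; hi <- 60 / hr_range[1]
  times <- beats$times
  if (length(times) < 2)
    return(structure(list(beats = beats,
                          interpolated = logical(length(times)),
                          amplitude_used = NA_real_),
                     class = "beat_detections"))
  out_t <- times[1]; out_f <- FALSE
  hist <- numeric(0)
  for (i in 2:length(times)) {
    ipi <- times[i] - times[i - 1]
    if (length(hist)) {
      med <- stats::median(hist)
      if (ipi >= 2 * med - .eps && ipi <= 3 * med + .eps) {
        out_t <- c(out_t, (times[i] + times[i - 1]) / 2)
        out_f <- c(out_f, TRUE)
      }
    }
    if (ipi >= lo && ipi <= hi) hist <- utils::tail(c(hist, ipi), history)
    out_t <- c(out_t, times[i]); out_f <- c(out_f, FALSE)
  }
  structure(list(beats = beat_train(out_t), interpolated = out_f,
                 amplitude_used = NA_real_),
            class = "beat_detections")
}

#' @export
print.beat_detections <- function(x, ...) {
  cat(sprintf("<beat_detections> %d beats (%d interpolated)",
              length(x$beats$times), sum(x$interpolated)))
  if (is.finite(x$amplitude_used))
    cat(sprintf(", amplitude %.4g", x$amplitude_used))
  cat("\n")
  invisible(x)
}

#' Bundle an ANN output stream with its smoothed trace
#'
#' @param probs a [time_series()] of per-sample probabilities.
#' @param ma_width moving-average width in samples.
#' @return list of class `detection_trace` with `probs` and `smoothed`.
#' @export
detection_trace <- function(probs, ma_width = 10L) {
  stopifnot(inherits(probs, "radar_ts"))
  structure(list(probs = probs, smoothed = smooth_ma(probs, ma_width)),
            class = "detection_trace")
}

#' Calibrate the detection amplitude on a small reference sample
#'
#' Evaluates every candidate threshold on the calibration traces with the full
#' detection chain (peak picking plus interpolation) and returns the grid
#' value minimizing the mean absolute count error against the reference beat
#' trains; ties go to the larger threshold (fewer false peaks). The chosen
#' amplitude is then reused unchanged for every test subject.
#'
#' @param traces list of `detection_trace`.
#' @param refs list of reference [beat_train()], one per trace.
#' @param grid candidate thresholds; defaults to 50 evenly spaced values
#'   spanning the observed smoothed-trace range.
#' @param hr_range,history passed to the detection chain.
#' @return the selected threshold.
#' @export
calibrate_amplitude <- function(traces, refs, grid = NULL,
                                hr_range = c(40, 120), history = 5L) {
  stopifnot(length(traces) >= 1, length(traces) == length(refs))
  if (is.null(grid)) {
    rng <- range(unlist(lapply(traces, function(tr) range(tr$smoothed$values))))
    if (diff(rng) <= 0) stop("flat traces: cannot build a threshold grid")
    grid <- seq(rng[1] + diff(rng) / 51, rng[2] - diff(rng) / 51,
                length.out = 50)
    grid <- grid[grid > 0]
  }
  if (!length(grid)) stop("empty threshold grid")
  grid <- sort(unique(grid))
  err <- vapply(grid, function(g) {
    mean(vapply(seq_along(traces), function(k) {
      det <- detect_peaks(traces[[k]]$smoothed, g, hr_range)
      det <- interpolate_missed(det, hr_range, history)
      n_ref <- length(refs[[k]]$times)
      if (n_ref == 0) return(NA_real_)
      abs(100 * (length(det$beats$times) - n_ref) / n_ref)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- max(which(err <= min(err) + 1e-12)) # ties -> larger threshold
  grid[best]
}
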