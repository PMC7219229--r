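# Uniformly sampled scalar channel: the substrate for ECG, I, Q, targets and
# ANN outputs. Sample k (0-based) occurs at t0 + k/rate, seconds.

#' Construct a uniformly sampled time series
#'
#' @param values numeric vector of samples (channel units). May be empty.
#' @param rate sampling rate in Hz; must be positive.
#' @param t0 time of the first sample, seconds.
#' @return an object of class `radar_ts` with fields `values`, `rate`, `t0`.
#' @export
#' @examples
#' ts <- time_series(sin(2 * pi * 1 * (0:999) / 1000), rate = 1000)
#' ts_times(ts)[1:3]
time_series <- function(values, rate, t0 = 0) {
  stopifnot(is.numeric(values), is.numeric(rate), length(rate) == 1L,
            is.numeric(t0), length(t0) == 1L)
  if (!is.finite(rate) || rate <= 0) stop("rate must be a positive finite number")
  if (length(values) && any(!is.finite(values)))
    stop("time series values must be finite")
  structure(list(values = as.double(values), rate = as.double(rate),
                 t0 = as.double(t0)),
            class = "radar_ts")
}

#' @export
print.radar_ts <- function(x, ...) {
  cat(sprintf("<radar_ts> %d samples @ %g Hz, t0 = %.6g s, span %.6g s\n",
              length(x$values), x$rate, x$t0, length(x$values) / x$rate))
  invisible(x)
}

#' Sample times of a time series
#'
#' @param ts a `radar_ts`.
#' @return numeric vector `t0 + (0:(n-1))/rate`.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "radar_ts"))
  if (!length(ts$values)) return(numeric(0))
  ts$t0 + (seq_along(ts$values) - 1) / ts$rate
}

# Exclusive end of the sampled span (time of one-past-last sample).
ts_end <- function(ts) ts$t0 + length(ts$values) / ts$rate

#' Construct a heartbeat event train
#'
#' Ordered event times (reference R-peak times or detected mechanical-beat
#' times) in seconds. Times must be strictly increasing.
#'
#' @param times numeric vector of event times, seconds.
#' @return an object of class `beat_train`.
#' @export
beat_train <- function(times = numeric(0)) {
  stopifnot(is.numeric(times))
  times <- as.double(times)
  if (length(times) && any(!is.finite(times))) stop("beat times must be finite")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("beat times must be strictly increasing")
  structure(list(times = times), class = "beat_train")
}

#' @export
print.beat_train <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<beat_train> %d events", n))
  if (n > 1) {
    ipi <- diff(x$times)
    cat(sprintf(", span %.1f s, median IPI %.3f s", diff(range(x$times)),
                stats::median(ipi)))
  }
  cat("\n")
  invisible(x)
}

#' Construct a subject recording
#'
#' One subject's aligned channels: single-lead ECG (mV, typically 250 Hz) plus
#' the radar in-phase and quadrature baseband channels (ADC scale, typically
#' 1 kHz). Simulated recordings additionally carry the ground-truth beat train.
#'
#' @param subject_id opaque subject label.
#' @param ecg,i_ch,q_ch `radar_ts` channels.
#' @param truth_beats optional `beat_train` of true R times (simulator only).
#' @return an object of class `subject_recording`.
#' @export
subject_recording <- function(subject_id, ecg, i_ch, q_ch, truth_beats = NULL) {
  stopifnot(inherits(ecg, "radar_ts"), inherits(i_ch, "radar_ts"),
            inherits(q_ch, "radar_ts"))
  if (!is.null(truth_beats)) stopifnot(inherits(truth_beats, "beat_train"))
  structure(list(subject_id = as.character(subject_id), ecg = ecg,
                 i_ch = i_ch, q_ch = q_ch, truth_beats = truth_beats),
            class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> %s\n", x$subject_id))
  cat(sprintf("  ecg: %d @ %g Hz | i: %d @ %g Hz | q: %d @ %g Hz\n",
              length(x$ecg$values), x$ecg$rate,
              length(x$i_ch$values), x$i_ch$rate,
              length(x$q_ch$values), x$q_ch$rate))
  if (!is.null(x$truth_beats))
    cat(sprintf("  truth beats: %d\n", length(x$truth_beats$times)))
  invisible(x)
}

rec_channels <- function(rec) list(ecg = rec$ecg, i = rec$i_ch, q = rec$q_ch)
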