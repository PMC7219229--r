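# Rate conversion and timestamp alignment.
#
# Time convention used throughout: seconds as real numbers, 0-based sample
# indices, half-open windows [start, stop).

# Zero-phase filtering with odd-symmetric (mirror) edge padding, so that
# start-up transients decay inside the padding instead of contaminating the
# signal (plain forward-backward filtering starts from rest and would distort
# even a constant input at the edges).
filtfilt_padded <- function(bf, x, pad = 300L) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(signal::filtfilt(bf, x))
  left <- 2 * x[1] - x[(pad + 1L):2]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(pad + 1L):(pad + n)]
}

#' Decimate a time series to a lower rate
#'
#' Anti-alias low-pass filters the input (zero-phase forward-backward
#' Butterworth, cutoff 0.4 x target rate) and keeps every
#' `rate/target_rate`-th sample. The rate ratio must be an integer; resampling
#' by rational factors is out of scope. Zero-phase filtering is used so that
#' beat latencies are preserved, which the delayed training target depends on.
#'
#' @param ts a [time_series()].
#' @param target_rate desired rate, Hz; `ts$rate` must be an integer multiple.
#' @return a [time_series()] at `target_rate` with the same `t0`; output length
#'   is `ceiling(n / factor)`.
#' @export
#' @examples
#' x <- time_series(rep(1, 1000), rate = 1000)
#' length(decimate(x, 100)$values) # 100
decimate <- function(ts, target_rate) {
  stopifnot(inherits(ts, "radar_ts"), is.numeric(target_rate),
            length(target_rate) == 1L, target_rate > 0)
  factor <- ts$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf("rate %g Hz is not an integer multiple of target %g Hz",
                 ts$rate, target_rate))
  factor <- as.integer(round(factor))
  if (factor == 1L) return(ts)
  n <- length(ts$values)
  if (n == 0L) return(time_series(numeric(0), target_rate, ts$t0))
  v <- ts$values
  # filtfilt needs a few filter lengths of data; constants and very short
  # series pass through (no aliasing content to remove).
  if (n > 24L) {
    bf <- signal::butter(4, 0.8 * target_rate / ts$rate, type = "low")
    v <- filtfilt_padded(bf, v)
  }
  keep <- seq.int(1L, n, by = factor)
  time_series(v[keep], target_rate, ts$t0)
}

#' Align the channels of a recording onto a common clock origin
#'
#' Re-references every channel to the latest channel start time, dropping
#' leading samples before the common origin and trailing overhang so that all
#' spans agree to within one sample period. Alignment is by nearest sample (no
#' sub-sample interpolation), mirroring alignment of logged timestamps.
#' Idempotent.
#'
#' @param rec a [subject_recording()] whose channels carry absolute timestamps.
#' @return the aligned [subject_recording()].
#' @export
align_recording <- function(rec) {
  stopifnot(inherits(rec, "subject_recording"))
  chans <- rec_channels(rec)
  nonempty <- Filter(function(ch) length(ch$values) > 0, chans)
  if (!length(nonempty)) return(rec)
  origin <- max(vapply(nonempty, function(ch) ch$t0, 0))
  stop_t <- min(vapply(nonempty, ts_end, 0))
  if (stop_t <= origin + .eps)
    stop("channels do not overlap in time; cannot align")
  trim <- function(ch) {
    if (!length(ch$values)) return(ch)
    k0 <- as.integer(round((origin - ch$t0) * ch$rate))
    k0 <- max(0L, k0)
    new_t0 <- ch$t0 + k0 / ch$rate
    n_keep <- as.integer(floor((stop_t - new_t0) * ch$rate + .eps))
    n_keep <- min(n_keep, length(ch$values) - k0)
    time_series(ch$values[(k0 + 1L):(k0 + n_keep)], ch$rate, new_t0)
  }
  out <- subject_recording(rec$subject_id, trim(chans$ecg), trim(chans$i),
                           trim(chans$q))
  if (!is.null(rec$truth_beats)) {
    keep <- rec$truth_beats$times >= origin & rec$truth_beats$times < stop_t
    out$truth_beats <- beat_train(rec$truth_beats$times[keep])
  }
  out
}

#' Crop a recording to a half-open time window
#'
#' Restricts every channel (and the truth beat train, when present) to
#' `[start, stop)`. Sample values are copied exactly; no filtering is applied.
#'
#' @param rec a [subject_recording()].
#' @param start,stop window bounds in seconds; must satisfy `start < stop` and
#'   lie within the recording span.
#' @return the cropped [subject_recording()] with updated `t0` values.
#' @export
crop_recording <- function(rec, start, stop) {
  stopifnot(inherits(rec, "subject_recording"),
            is.numeric(start), is.numeric(stop))
  if (!(start < stop)) stop("crop window requires start < stop")
  chans <- rec_channels(rec)
  nonempty <- Filter(function(ch) length(ch$values) > 0, chans)
  if (length(nonempty)) {
    span_start <- min(vapply(nonempty, function(ch) ch$t0, 0))
    span_end <- max(vapply(nonempty, ts_end, 0))
    if (start < span_start - .eps || stop > span_end + .eps)
      stop(sprintf("crop window [%g, %g) outside recording span [%g, %g)",
                   start, stop, span_start, span_end))
  }
  cut <- function(ch) {
    if (!length(ch$values)) return(ch)
    k0 <- as.integer(ceiling((start - ch$t0) * ch$rate - .eps))
    k1 <- as.integer(ceiling((stop - ch$t0) * ch$rate - .eps)) - 1L
    k0 <- max(k0, 0L)
    k1 <- min(k1, length(ch$values) - 1L)
    if (k1 < k0) return(time_series(numeric(0), ch$rate, start))
    time_series(ch$values[(k0 + 1L):(k1 + 1L)], ch$rate, ch$t0 + k0 / ch$rate)
  }
  out <- subject_recording(rec$subject_id, cut(chans$ecg), cut(chans$i),
                           cut(chans$q))
  if (!is.null(rec$truth_beats)) {
    keep <- rec$truth_beats$times >= start & rec$truth_beats$times < stop
    out$truth_beats <- beat_train(rec$truth_beats$times[keep])
  }
  out
}
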