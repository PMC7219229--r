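# Input windowing: 200-sample I||Q vectors at the 100 Hz working rate.

#' Build the windowed input set for the detector
#'
#' One causal, right-aligned window per sample index `k >= memory*rate`
#' (stride 1): the first half of each row holds the in-phase samples and the
#' second half the quadrature samples covering the identical time span, each
#' ordered oldest to newest. The row target is the binarized-target value at
#' the newest sample. With the default 1 s memory at 100 Hz each row is a
#' 200-sample vector and `n` input samples yield `n - 99` windows.
#'
#' @param i100,q100 `radar_ts` radar channels at the working rate, aligned and
#'   of equal length.
#' @param target a binarized target [time_series()] on the same grid, or
#'   `NULL` (prediction only; targets set to 0).
#' @param memory window length, s (default 1.0).
#' @return an object of class `window_set`: `inputs` (matrix, `n_windows x
#'   2*memory*rate`), `targets`, `timestamps` (time of the newest sample per
#'   row), `rate`, `memory`, and optional `groups`.
#' @export
build_windows <- function(i100, q100, target = NULL, memory = 1.0) {
  stopifnot(inherits(i100, "radar_ts"), inherits(q100, "radar_ts"))
  rate <- i100$rate
  if (q100$rate != rate) stop("I and Q rates differ")
  n <- length(i100$values)
  if (length(q100$values) != n) stop("I and Q lengths differ")
  if (abs(i100$t0 - q100$t0) > 0.5 / rate) stop("I and Q are not aligned")
  if (!is.null(target)) {
    if (target$rate != rate) stop("target rate differs from channel rate")
    if (length(target$values) != n) stop("target length differs from channels")
    if (abs(target$t0 - i100$t0) > 0.5 / rate)
      stop("target is not aligned with the channels")
  }
  m <- as.integer(round(memory * rate))
  if (m < 1 || n < m) stop("need at least memory*rate samples per channel")
  nw <- n - m + 1L
  idx <- outer(0:(nw - 1L), 1:m, `+`) # row k: samples k..k+m-1 (oldest->newest)
  inputs <- cbind(matrix(i100$values[idx], nw, m),
                  matrix(q100$values[idx], nw, m))
  tg <- if (is.null(target)) numeric(nw) else target$values[m:n]
  structure(list(inputs = inputs, targets = as.double(tg),
                 timestamps = i100$t0 + ((m:n) - 1) / rate,
                 rate = rate, memory = memory, groups = NULL),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x %d inputs @ %g Hz (memory %g s)\n",
              nrow(x$inputs), ncol(x$inputs), x$rate, x$memory))
  invisible(x)
}

# Row-bind per-subject window sets, tagging rows with subject ids so the
# validation split can stratify by subject.
combine_windows <- function(ws_list, ids = NULL) {
  stopifnot(length(ws_list) >= 1)
  dims <- vapply(ws_list, function(w) ncol(w$inputs), 0L)
  if (length(unique(dims)) != 1) stop("window sets have differing input widths")
  if (is.null(ids)) ids <- as.character(seq_along(ws_list))
  out <- ws_list[[1]]
  out$inputs <- do.call(rbind, lapply(ws_list, `[[`, "inputs"))
  out$targets <- unlist(lapply(ws_list, `[[`, "targets"), use.names = FALSE)
  out$timestamps <- unlist(lapply(ws_list, `[[`, "timestamps"),
                           use.names = FALSE)
  out$groups <- rep(ids, vapply(ws_list, function(w) nrow(w$inputs), 0L))
  out
}

# Deterministic row subset of a window set.
subset_windows <- function(ws, rows) {
  ws$inputs <- ws$inputs[rows, , drop = FALSE]
  ws$targets <- ws$targets[rows]
  ws$timestamps <- ws$timestamps[rows]
  if (!is.null(ws$groups)) ws$groups <- ws$groups[rows]
  ws
}

#' Build open-loop (teacher-forced) NARX training windows
#'
#' The exogenous part of each row is identical to the feed-forward window; the
#' trailing `feedback` entries hold the target values at the `feedback`
#' samples preceding the row's newest sample (oldest to newest), emulating the
#' network's own fed-back outputs under teacher forcing.
#'
#' @inheritParams build_windows
#' @param feedback feedback depth (default 10).
#' @return a `window_set` whose rows are `[exogenous window || feedback]`.
#' @export
build_narx_windows <- function(i100, q100, target, memory = 1.0,
                               feedback = 10L) {
  stopifnot(!is.null(target), feedback >= 1)
  ws <- build_windows(i100, q100, target, memory)
  m <- as.integer(round(memory * i100$rate))
  n <- length(i100$values)
  nw <- nrow(ws$inputs)
  # rows whose newest sample index k (in m..n) has k-feedback >= 1
  first_ok <- max(1L, feedback - m + 2L)
  keep <- first_ok:nw
  k_new <- (m:n)[keep]
  fb <- t(vapply(k_new, function(k) target$values[(k - feedback):(k - 1L)],
                 numeric(feedback)))
  out <- subset_windows(ws, keep)
  out$inputs <- cbind(out$inputs, fb)
  out$feedback <- as.integer(feedback)
  out
}
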