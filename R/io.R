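# Plain-text recording files: UTF-8 delimited text with `#key=value` metadata
# lines, then one `channel,t,value` row per sample. One file per subject.
# Beat trains are one event time (s) per line.

#' Read a subject recording from a delimited text file
#'
#' The dialect is: leading `#key=value` comment lines carrying `subject_id` and
#' per-channel rates (`rate_ecg`, `rate_i`, `rate_q`), then a `channel,t,value`
#' header and one row per sample. Channels may be empty (headers only).
#' Timestamps within a channel must be strictly increasing and consistent with
#' the declared rate.
#'
#' @param path file path.
#' @return a [subject_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file does not exist: ", path)
  head_lines <- readLines(path, n = 200L, warn = FALSE)
  meta_lines <- grep("^#", head_lines)
  n_meta <- if (length(meta_lines)) max(meta_lines) else 0L
  meta <- list()
  for (ln in head_lines[seq_len(n_meta)]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  for (key in c("rate_ecg", "rate_i", "rate_q")) {
    if (is.null(meta[[key]])) stop("missing metadata line #", key, "= in ", path)
  }
  tab <- data.table::fread(path, skip = n_meta, header = TRUE, sep = ",",
                           colClasses = list(character = "channel"))
  need <- c("channel", "t", "value")
  missing_col <- setdiff(need, names(tab))
  if (length(missing_col))
    stop("missing column(s) in ", path, ": ", paste(missing_col, collapse = ", "))

  parse_channel <- function(name, rate) {
    rows <- which(tab$channel == name)
    if (!length(rows)) return(time_series(numeric(0), rate, 0))
    tt <- tab$t[rows]
    if (length(tt) > 1) {
      d <- diff(tt)
      bad <- which(d <= 0)
      if (length(bad)) {
        # +1 header line, +1 for 1-based, offset by metadata block
        file_line <- n_meta + 1L + rows[bad[1] + 1L]
        stop(sprintf("non-monotone timestamp in channel '%s' at line %d of %s",
                     name, file_line, path))
      }
      if (max(abs(d - 1 / rate)) > 0.25 / rate)
        stop(sprintf("rate mismatch in channel '%s' of %s: declared %g Hz but timestamps disagree",
                     name, path, rate))
    }
    time_series(tab$value[rows], rate, tt[1])
  }

  subject_recording(
    subject_id = if (is.null(meta$subject_id)) basename(path) else meta$subject_id,
    ecg  = parse_channel("ecg", as.numeric(meta$rate_ecg)),
    i_ch = parse_channel("i",   as.numeric(meta$rate_i)),
    q_ch = parse_channel("q",   as.numeric(meta$rate_q))
  )
}

#' Write a subject recording to a delimited text file
#'
#' Values round-trip through [read_recording()] to better than 1e-9 relative
#' error. The ground-truth beat train, when present, is not written here; use
#' [write_beats()] for that.
#'
#' @param rec a [subject_recording()].
#' @param path destination file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "subject_recording"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("#subject_id=", rec$subject_id),
    paste0("#rate_ecg=", format(rec$ecg$rate, digits = 15)),
    paste0("#rate_i=",   format(rec$i_ch$rate, digits = 15)),
    paste0("#rate_q=",   format(rec$q_ch$rate, digits = 15))
  ), con)
  blocks <- list()
  for (name in c("ecg", "i", "q")) {
    ch <- rec_channels(rec)[[name]]
    if (length(ch$values)) {
      blocks[[name]] <- data.table::data.table(
        channel = name, t = ts_times(ch), value = ch$values)
    }
  }
  close(con); on.exit(NULL)
  body <- if (length(blocks)) data.table::rbindlist(blocks) else
    data.table::data.table(channel = character(0), t = numeric(0),
                           value = numeric(0))
  data.table::fwrite(body, path, append = TRUE, col.names = TRUE, sep = ",")
  invisible(path)
}

#' Read / write a beat-train file (one event time in seconds per line)
#'
#' @param path file path.
#' @return `read_beats` returns a [beat_train()].
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) stop("beat file does not exist: ", path)
  x <- scan(path, what = double(), quiet = TRUE, comment.char = "#")
  beat_train(x)
}

#' @rdname read_beats
#' @param beats a [beat_train()] to write.
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_train"))
  writeLines(format(beats$times, digits = 17, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}
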