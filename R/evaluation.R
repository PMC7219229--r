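# Scoring detections against reference beats: count error, inter-pulse
# interval statistics, paired tests with a normality gate, and subject-wise
# three-fold cross-validation of the whole chain.

#' Signed percentage error in the number of detected heartbeats
#'
#' `100 * (N_det - N_ref) / N_ref`; negative values mean under-detection.
#'
#' @param detected a [beat_train()] or a bare detected count.
#' @param reference a [beat_train()] or a bare reference count (non-empty /
#'   non-zero).
#' @return signed percentage.
#' @export
#' @examples
#' count_error(5040, 5144) # about -2
count_error <- function(detected, reference) {
  n_det <- if (inherits(detected, "beat_train")) length(detected$times)
           else as.numeric(detected)
  n_ref <- if (inherits(reference, "beat_train")) length(reference$times)
           else as.numeric(reference)
  if (!length(n_ref) || n_ref == 0) stop("reference beat train is empty")
  100 * (n_det - n_ref) / n_ref
}

#' Inter-pulse interval series of a beat train
#'
#' Time elapsed between every two adjacent heartbeats (first differences).
#'
#' @param beats a [beat_train()] with at least two events.
#' @return numeric vector of IPIs, seconds; length `count - 1`.
#' @export
ipi_series <- function(beats) {
  stopifnot(inherits(beats, "beat_train"))
  if (length(beats$times) < 2) stop("need at least 2 beats for an IPI series")
  diff(beats$times)
}

# Greedy nearest-time matching of detected to reference beats within `tol`
# seconds; each side used at most once. Returns, per reference beat, the index
# of the matched detected beat (NA if unmatched).
match_beats <- function(detected, reference, tol = 0.5) {
  dt <- detected$times; rt <- reference$times
  m <- rep(NA_integer_, length(rt))
  if (!length(dt) || !length(rt)) return(m)
  d <- abs(outer(dt, rt, `-`))
  cand <- which(d <= tol, arr.ind = TRUE)
  if (!nrow(cand)) return(m)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_d <- logical(length(dt))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_d[i] && is.na(m[j])) { m[j] <- i; used_d[i] <- TRUE }
  }
  m
}

#' Mean relative error of matched inter-pulse intervals
#'
#' Detected beats are matched to reference beats by greedy nearest-time
#' pairing within `match_tol` (each reference used once); for every pair of
#' consecutive reference beats that are both matched, the relative IPI error
#' `|IPI_det - IPI_ref| / IPI_ref` is accumulated. The pairing rule is a
#' package convention (the tolerance equals the minimum-IPI constraint); the
#' metric is invariant to a global time shift of either train.
#'
#' @param detected,reference [beat_train()]s with at least two events each.
#' @param match_tol matching tolerance, s.
#' @return mean relative error as a percentage.
#' @export
ipi_mre <- function(detected, reference, match_tol = 0.5) {
  stopifnot(inherits(detected, "beat_train"), inherits(reference, "beat_train"))
  if (length(detected$times) < 2 || length(reference$times) < 2)
    stop("need at least 2 beats in each train")
  m <- match_beats(detected, reference, match_tol)
  j <- which(!is.na(m[-length(m)]) & !is.na(m[-1]))
  if (!length(j)) stop("no matched consecutive beat pairs within tolerance")
  ipi_ref <- reference$times[j + 1] - reference$times[j]
  ipi_det <- detected$times[m[j + 1]] - detected$times[m[j]]
  100 * mean(abs(ipi_det - ipi_ref) / ipi_ref)
}

#' Paired comparison with a normality gate
#'
#' Applies the Lilliefors test to the paired differences at level `alpha`; if
#' normality is rejected (the typical case for IPI data) the Wilcoxon
#' signed-rank test is used (exact for n <= 25), otherwise the paired t-test.
#' All-zero differences are degenerate and reported with p = 1 and a flag.
#'
#' @param sample_a,sample_b paired numeric vectors of equal length >= 5.
#' @param alpha significance level for both the gate and the decision.
#' @return list: `test` (name), `p_value`, `significant`, `normality_p`,
#'   `degenerate`.
#' @export
paired_compare <- function(sample_a, sample_b, alpha = 0.05) {
  stopifnot(length(sample_a) == length(sample_b), length(sample_a) >= 5)
  d <- sample_a - sample_b
  if (all(d == 0))
    return(list(test = "degenerate", p_value = 1, significant = FALSE,
                normality_p = NA_real_, degenerate = TRUE))
  norm_p <- if (stats::sd(d) < 1e-14) 0 else
    tryCatch(nortest::lillie.test(d)$p.value, error = function(e) 0)
  if (norm_p < alpha) {
    ht <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                              paired = TRUE,
                                              exact = length(d) <= 25))
    test <- "wilcoxon-signed-rank"
  } else {
    ht <- stats::t.test(sample_a, sample_b, paired = TRUE)
    test <- "paired-t"
  }
  list(test = test, p_value = unname(ht$p.value),
       significant = unname(ht$p.value < alpha), normality_p = norm_p,
       degenerate = FALSE)
}

#' Assign subjects to cross-validation folds
#'
#' Subject-level assignment by seeded shuffle and round-robin, so fold sizes
#' differ by at most one and all data from a subject shares a fold.
#'
#' @param subject_ids character vector of subject labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return named integer vector: subject id -> fold index.
#' @export
make_folds <- function(subject_ids, n_folds = 3, seed = 1) {
  stopifnot(length(subject_ids) >= n_folds, n_folds >= 2)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  shuffled <- with_seed(seed, sample(subject_ids))
  folds <- rep(seq_len(n_folds), length.out = length(shuffled))
  stats::setNames(folds[order(match(subject_ids, shuffled))], subject_ids)
}

# Decimate a recording's radar channels to the working rate, detect the ECG
# reference beats, and pre-build the window inputs. Shared by training,
# calibration and evaluation so every stage sees identical preprocessing.
prepare_subject <- function(rec, rate = 100, memory = 1.0, delay = 0.2,
                            width = 0.4, narx_feedback = NULL) {
  i100 <- decimate(rec$i_ch, rate)
  q100 <- decimate(rec$q_ch, rate)
  ref_beats <- pan_tompkins(rec$ecg)
  span <- c(i100$t0, ts_end(i100))
  target <- binarize_targets(ref_beats, rate, span, delay, width)
  out <- list(subject_id = rec$subject_id, i = i100, q = q100,
              ref_beats = ref_beats, truth_beats = rec$truth_beats,
              span = span, target = target,
              windows = build_windows(i100, q100, target, memory = memory),
              delay = delay, width = width)
  if (!is.null(narx_feedback)) {
    # teacher-forced rows for open-loop NARX training; closed-loop evaluation
    # still runs on the plain (exogenous) windows above
    out$windows_narx <- build_narx_windows(i100, q100, target,
                                           memory = memory,
                                           feedback = narx_feedback)
  }
  out
}

# Predict + smooth + peak-pick + interpolate on a prepared subject.
detect_on_prepared <- function(model, prep, amplitude, ma_width = 10L,
                               hr_range = c(40, 120), history = 5L) {
  probs <- if (model$kind == "NARX") narx_predict(model, prep$windows)
           else ann_predict(model, prep$windows)
  trace <- detection_trace(
    time_series(probs, prep$windows$rate, prep$windows$timestamps[1]),
    ma_width)
  det <- detect_peaks(trace$smoothed, amplitude, hr_range)
  det <- interpolate_missed(det, hr_range, history)
  det$amplitude_used <- amplitude
  det$trace <- trace
  det
}

#' Run the full detection chain on one recording
#'
#' Decimates the radar channels, applies the trained network per sample,
#' smooths, peak-picks and interpolates. `amplitude = "auto"` calibrates the
#' threshold against this recording's own ECG reference (diagnostic use; for
#' honest evaluation calibrate on held-out training data instead).
#'
#' @param model a trained `ann_model`.
#' @param rec a [subject_recording()].
#' @param amplitude detection amplitude, or `"auto"`.
#' @param rate working rate, Hz.
#' @param memory input window length, s.
#' @param ma_width smoothing width, samples.
#' @param hr_range physiological heart-rate range, beats/min.
#' @return a `beat_detections` object (with the `detection_trace` attached).
#' @export
detect_heartbeats <- function(model, rec, amplitude = "auto", rate = 100,
                              memory = 1.0, ma_width = 10L,
                              hr_range = c(40, 120)) {
  prep <- prepare_subject(rec, rate, memory)
  if (identical(amplitude, "auto")) {
    probs <- if (model$kind == "NARX") narx_predict(model, prep$windows)
             else ann_predict(model, prep$windows)
    trace <- detection_trace(
      time_series(probs, rate, prep$windows$timestamps[1]), ma_width)
    amplitude <- calibrate_amplitude(list(trace), list(prep$ref_beats),
                                     hr_range = hr_range)
  }
  detect_on_prepared(model, prep, amplitude, ma_width, hr_range)
}

subject_metrics <- function(det, prep, hr_range = c(40, 120),
                            include_interpolated = TRUE) {
  beats <- if (include_interpolated) det$beats else
    beat_train(det$beats$times[!det$interpolated])
  ref <- prep$ref_beats
  n_det <- length(beats$times); n_ref <- length(ref$times)
  ipi_d <- if (n_det >= 2) ipi_series(beats) else numeric(0)
  ipi_r <- if (n_ref >= 2) ipi_series(ref) else numeric(0)
  mre <- tryCatch(ipi_mre(beats, ref), error = function(e) NA_real_)
  # per-subject distribution comparison on matched consecutive IPI pairs
  m <- match_beats(beats, ref, tol = 0.5)
  j <- which(!is.na(m[-length(m)]) & !is.na(m[-1]))
  cmp <- if (length(j) >= 5)
    paired_compare(beats$times[m[j + 1]] - beats$times[m[j]],
                   ref$times[j + 1] - ref$times[j])
  else list(test = NA_character_, p_value = NA_real_, significant = NA)
  # detections inside the post-R target window (non-interpolated only)
  raw <- det$beats$times[!det$interpolated]
  in_win <- if (length(raw) && n_ref) {
    hits <- vapply(raw, function(t)
      any(t >= ref$times + prep$delay - .eps &
          t < ref$times + prep$delay + prep$width + .eps), logical(1))
    100 * mean(hits)
  } else NA_real_
  data.frame(
    subject = prep$subject_id,
    n_detected = n_det, n_reference = n_ref,
    count_error_pct = count_error(n_det, n_ref),
    ipi_median_det = if (length(ipi_d)) stats::median(ipi_d) else NA_real_,
    ipi_median_ref = if (length(ipi_r)) stats::median(ipi_r) else NA_real_,
    ipi_mre_pct = mre,
    ipi_test = cmp$test, ipi_p = cmp$p_value,
    no_sig_diff = !isTRUE(cmp$significant),
    in_window_pct = in_win,
    n_interpolated = sum(det$interpolated),
    stringsAsFactors = FALSE)
}

#' Subject-wise k-fold cross-validation of the detection chain
#'
#' Assigns subjects to folds by seeded shuffle; for each fold, trains the
#' requested topology on the other folds, calibrates the detection amplitude
#' on the first subject of each training fold, then scores every held-out
#' subject. Metrics are pooled over the predictions of all test folds. No
#' subject ever contributes to both training and testing.
#'
#' @param cohort list of [subject_recording()].
#' @param topology topology label (default `"FF 20 1"`).
#' @param cfg a [train_config()].
#' @param n_folds number of folds (default 3).
#' @param seed master seed for fold assignment, training and subsampling.
#' @param rate,memory,delay,width preprocessing parameters.
#' @param ma_width,hr_range,history postprocessing parameters.
#' @param train_stride keep every `train_stride`-th training window (the
#'   evaluation always runs at stride 1).
#' @param max_train_windows cap on training rows (random subsample beyond it).
#' @param amplitude_grid optional explicit calibration grid.
#' @param include_interpolated count interpolated beats in the metrics
#'   (reported separately per subject either way).
#' @param narx_feedback feedback depth for NARX topologies (training is
#'   teacher-forced open loop; evaluation runs closed loop).
#' @return list of class `eval_report`: `per_subject` (data.frame), `pooled`
#'   (list), `topology`, `folds`.
#' @export
crossvalidate <- function(cohort, topology = "FF 20 1", cfg = train_config(),
                          n_folds = 3, seed = 1, rate = 100, memory = 1.0,
                          delay = 0.2, width = 0.4, ma_width = 10L,
                          hr_range = c(40, 120), history = 5L,
                          train_stride = 1L, max_train_windows = Inf,
                          amplitude_grid = NULL,
                          include_interpolated = TRUE, narx_feedback = 10L) {
  ids <- vapply(cohort, function(r) r$subject_id, "")
  if (length(ids) < n_folds) stop("fewer subjects than folds")
  folds <- make_folds(ids, n_folds, derive_seed(seed, "folds"))
  is_narx <- parse_topology(topology)$kind == "NARX"
  prep <- lapply(cohort, prepare_subject, rate = rate, memory = memory,
                 delay = delay, width = width,
                 narx_feedback = if (is_narx) narx_feedback else NULL)
  names(prep) <- ids

  per_subject <- list()
  for (f in sort(unique(folds))) {
    train_ids <- names(folds)[folds != f]
    test_ids <- names(folds)[folds == f]
    stopifnot(length(intersect(train_ids, test_ids)) == 0)
    ws <- combine_windows(lapply(prep[train_ids], `[[`,
                                 if (is_narx) "windows_narx" else "windows"),
                          ids = train_ids)
    rows <- seq.int(1L, nrow(ws$inputs), by = as.integer(train_stride))
    if (length(rows) > max_train_windows) {
      rows <- sort(with_seed(derive_seed(seed, paste0("sub", f)),
                             sample(rows, max_train_windows)))
    }
    ws <- subset_windows(ws, rows)
    fit <- suppressWarnings(
      train_lm(topology, ws, replace_seed(cfg, derive_seed(seed, paste0("fold", f)))))
    # amplitude calibration on the first subject of each training fold
    calib_ids <- vapply(setdiff(sort(unique(folds)), f), function(g) {
      ids_g <- names(folds)[folds == g & names(folds) %in% train_ids]
      ids_g[1]
    }, "")
    traces <- lapply(prep[calib_ids], function(p) {
      probs <- if (fit$model$kind == "NARX") narx_predict(fit$model, p$windows)
               else ann_predict(fit$model, p$windows)
      detection_trace(time_series(probs, rate, p$windows$timestamps[1]),
                      ma_width)
    })
    amp <- calibrate_amplitude(traces, lapply(prep[calib_ids], `[[`, "ref_beats"),
                               grid = amplitude_grid, hr_range = hr_range,
                               history = history)
    for (sid in test_ids) {
      det <- detect_on_prepared(fit$model, prep[[sid]], amp, ma_width,
                                hr_range, history)
      row <- subject_metrics(det, prep[[sid]], hr_range, include_interpolated)
      row$fold <- f
      row$amplitude <- amp
      per_subject[[sid]] <- row
    }
  }
  per_subject <- do.call(rbind, per_subject[ids[order(folds[ids])]])
  rownames(per_subject) <- NULL

  pooled <- list(
    n_detected = sum(per_subject$n_detected),
    n_reference = sum(per_subject$n_reference),
    count_error_pct = count_error(sum(per_subject$n_detected),
                                  sum(per_subject$n_reference)),
    median_ipi_diff_s = stats::median(per_subject$ipi_median_det, na.rm = TRUE) -
      stats::median(per_subject$ipi_median_ref, na.rm = TRUE),
    ipi_mre_pct = stats::weighted.mean(per_subject$ipi_mre_pct,
                                       per_subject$n_reference, na.rm = TRUE),
    in_window_pct = stats::weighted.mean(per_subject$in_window_pct,
                                         per_subject$n_detected -
                                           per_subject$n_interpolated,
                                         na.rm = TRUE),
    n_no_sig_diff = sum(per_subject$no_sig_diff, na.rm = TRUE))
  pooled$median_ipi_diff_samples <- pooled$median_ipi_diff_s * rate
  pooled$median_ipi_diff_ms <- pooled$median_ipi_diff_s * 1000
  if (nrow(per_subject) >= 5) {
    pooled$count_test <- paired_compare(per_subject$n_detected,
                                        per_subject$n_reference)
    pooled$ipi_median_test <- paired_compare(per_subject$ipi_median_det,
                                             per_subject$ipi_median_ref)
  }
  structure(list(per_subject = per_subject, pooled = pooled,
                 topology = topology, folds = folds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d subjects in %d folds\n", x$topology,
              nrow(x$per_subject), length(unique(x$folds))))
  cat(sprintf("  pooled count error: %+.2f%% (%d detected / %d reference)\n",
              x$pooled$count_error_pct, x$pooled$n_detected,
              x$pooled$n_reference))
  cat(sprintf("  median IPI difference: %+.1f ms; IPI MRE %.1f%%\n",
              x$pooled$median_ipi_diff_ms, x$pooled$ipi_mre_pct))
  cat(sprintf("  subjects with no significant IPI-median difference: %d/%d\n",
              x$pooled$n_no_sig_diff, nrow(x$per_subject)))
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' @param report an `eval_report`.
#' @param path destination path (tab-separated).
#' @export
write_report <- function(report, path) {
  df <- report$per_subject
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) signif(col, 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
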