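# Forward-model simulator: beat trains -> ballistocardiographic chest
# displacement -> quadrature baseband I/Q -> matched synthetic ECG.
#
# The baseband model is
#   I(t) = A_I cos(theta0 + 4 pi x(t) / lambda + dtheta(t)) + DC_I + n_I(t)
#   Q(t) = A_Q sin(theta0 + 4 pi x(t) / lambda + dtheta(t) + dphi) + DC_Q + n_Q(t)
# where x(t) is the chest displacement in metres, lambda the carrier
# wavelength, A_I != A_Q models amplitude imbalance, dphi the quadrature phase
# imbalance, dtheta(t) residual phase noise (a random walk, off by default —
# negligible at short range) and n white measurement noise. The RF-level
# transmit/receive signals are represented only through these baseband
# parameters: the detector consumes baseband only.

SPEED_OF_LIGHT <- 299792458

#' Radar and baseband channel parameters
#'
#' @param carrier_f carrier frequency, Hz (default 24 GHz).
#' @param d0 nominal radar-target distance, m (default 0.75).
#' @param theta0 constant phase offset, rad; defaults to the offset implied by
#'   `d0` (`4*pi*d0/lambda` mod `2*pi`).
#' @param A_I,A_Q baseband amplitudes (`A_I != A_Q` models amplitude imbalance).
#' @param DC_I,DC_Q DC offsets, channel units.
#' @param dphi quadrature phase imbalance, rad.
#' @param phase_noise_sd per-sample scale of the residual phase-noise random
#'   walk, rad (default 0: negligible at short range).
#' @param noise_sd additive white measurement noise, channel units.
#' @param A_T transmit amplitude; carried for completeness, unused by baseband
#'   synthesis.
#' @param fs sampling rate of the baseband channels, Hz (default 1 kHz).
#' @return an object of class `radar_params`.
#' @export
radar_params <- function(carrier_f = 24e9, d0 = 0.75, theta0 = NULL,
                         A_I = 1.0, A_Q = 0.95, DC_I = 0.05, DC_Q = -0.03,
                         dphi = 0.05, phase_noise_sd = 0, noise_sd = 0.02,
                         A_T = 1.0, fs = 1000) {
  stopifnot(carrier_f > 0, fs > 0, phase_noise_sd >= 0, noise_sd >= 0)
  wavelength <- SPEED_OF_LIGHT / carrier_f
  if (is.null(theta0)) theta0 <- (4 * pi * d0 / wavelength) %% (2 * pi)
  structure(list(carrier_f = carrier_f, wavelength = wavelength, d0 = d0,
                 theta0 = theta0, A_I = A_I, A_Q = A_Q, DC_I = DC_I,
                 DC_Q = DC_Q, dphi = dphi, phase_noise_sd = phase_noise_sd,
                 noise_sd = noise_sd, A_T = A_T, fs = fs),
            class = "radar_params")
}

#' Vital-sign model driving the chest-displacement forward model
#'
#' Default magnitudes follow the physiology of a seated resting adult:
#' breathing displacement of order millimetres, heartbeat displacement
#' sub-millimetre, and an electro-mechanical (R-J) delay drawn per beat from
#' 203-290 ms.
#'
#' @param mean_hr mean heart rate, beats/min, within the resting range 40-120.
#' @param hrv_sd standard deviation of RR-interval jitter, s.
#' @param breath_rate breathing rate, Hz.
#' @param breath_amp breathing displacement amplitude, m.
#' @param beat_amp peak per-beat displacement, m; must be below `breath_amp`.
#' @param beat_kernel per-beat displacement waveform: `"two_lobe"` (default;
#'   two successive opposite-sign Gaussian lobes), `"gaussian"`, or
#'   `"damped_sine"`.
#' @param rj_delay_range interval the per-beat R-J delay is drawn from, s.
#' @return an object of class `vital_model`.
#' @export
vital_model <- function(mean_hr = 75, hrv_sd = 0.04, breath_rate = 0.25,
                        breath_amp = 1.5e-3, beat_amp = 3e-4,
                        beat_kernel = "two_lobe",
                        rj_delay_range = c(0.203, 0.290)) {
  stopifnot(mean_hr >= 40, mean_hr <= 120, hrv_sd >= 0, breath_rate > 0,
            breath_amp >= 0, beat_amp >= 0)
  if (breath_amp > 0 && beat_amp >= breath_amp)
    stop("beat_amp must be smaller than breath_amp")
  stopifnot(length(rj_delay_range) == 2, rj_delay_range[1] >= 0,
            rj_delay_range[2] <= 0.5, rj_delay_range[1] <= rj_delay_range[2])
  beat_kernel <- match.arg(beat_kernel, c("two_lobe", "gaussian", "damped_sine"))
  structure(list(mean_hr = mean_hr, hrv_sd = hrv_sd, breath_rate = breath_rate,
                 breath_amp = breath_amp, beat_amp = beat_amp,
                 beat_kernel = beat_kernel, rj_delay_range = rj_delay_range),
            class = "vital_model")
}

#' Generate a jittered heartbeat event train
#'
#' RR intervals are `60/mean_hr` plus Gaussian jitter of scale `hrv_sd`,
#' truncated to the resting physiological band `[0.5, 1.5]` s (40-120
#' beats/min). The first event falls uniformly inside the first RR interval.
#'
#' @param model a [vital_model()].
#' @param duration recording duration, s.
#' @param seed integer seed; the train is reproducible per seed.
#' @return a [beat_train()] with all events in `[0, duration)`.
#' @export
generate_beat_train <- function(model, duration, seed = 1) {
  stopifnot(inherits(model, "vital_model"), duration > 0)
  if (model$hrv_sd < 0) stop("hrv_sd must be non-negative")
  mean_rr <- 60 / model$mean_hr
  with_seed(seed, {
    n_max <- ceiling(duration / 0.5) + 2L
    rr <- mean_rr + stats::rnorm(n_max, 0, model$hrv_sd)
    rr <- pmin(pmax(rr, 0.5), 1.5)
    first <- stats::runif(1, 0, rr[1])
    times <- first + c(0, cumsum(rr[-1]))
    beat_train(times[times < duration])
  })
}

# Per-beat displacement kernels on the support [0, 0.30] s after onset.
# The effective support is kept inside 0.30 s so that for every R-J delay in
# the default range the whole mechanical signature stays inside the 400 ms
# training-target window that opens 200 ms after the R event.
KERNEL_SUPPORT <- 0.30

beat_kernel_fn <- function(kind) {
  switch(kind,
    two_lobe = function(tau) {
      # two successive opposite-sign lobes (J-wave recoil then rebound)
      k <- exp(-(tau - 0.09)^2 / (2 * 0.03^2)) - exp(-(tau - 0.21)^2 / (2 * 0.03^2))
      k * tukey_taper(tau)
    },
    gaussian = function(tau) {
      exp(-(tau - 0.15)^2 / (2 * 0.04^2)) * tukey_taper(tau)
    },
    damped_sine = function(tau) {
      sin(2 * pi * 8 * tau) * exp(-tau / 0.06) * tukey_taper(tau)
    },
    stop("unknown beat kernel: ", kind))
}

# Cosine-tapered window, exactly zero outside [0, KERNEL_SUPPORT]; removes the
# tail discontinuity of truncated Gaussians so phase demodulation round-trips
# cleanly.
tukey_taper <- function(tau, ramp = 0.05) {
  w <- numeric(length(tau))
  inside <- tau >= 0 & tau <= KERNEL_SUPPORT
  w[inside] <- 1
  lo <- inside & tau < ramp
  hi <- inside & tau > KERNEL_SUPPORT - ramp
  w[lo] <- 0.5 * (1 - cos(pi * tau[lo] / ramp))
  w[hi] <- 0.5 * (1 - cos(pi * (KERNEL_SUPPORT - tau[hi]) / ramp))
  w
}

#' Synthesize chest-wall displacement from a beat train
#'
#' `x(t) = breath_amp * sin(2 pi breath_rate t + phi_b) +
#'  sum_k kernel(t - t_k - d_k)` where the per-beat electro-mechanical delay
#' `d_k` is drawn uniformly from the model's R-J delay range and the kernel is
#' scaled to peak at `beat_amp`.
#'
#' @param beats a [beat_train()] of R-event times.
#' @param model a [vital_model()].
#' @param fs sampling rate, Hz.
#' @param duration duration, s.
#' @param seed integer seed (breathing phase and per-beat delays).
#' @return a [time_series()] of displacement in metres.
#' @export
chest_displacement <- function(beats, model, fs, duration, seed = 1) {
  stopifnot(inherits(beats, "beat_train"), inherits(model, "vital_model"),
            fs > 0, duration > 0)
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  kern <- beat_kernel_fn(model$beat_kernel)
  # normalize the kernel to unit peak once, on a fine grid
  tau_grid <- seq(0, KERNEL_SUPPORT, by = 1e-4)
  peak <- max(abs(kern(tau_grid)))
  with_seed(seed, {
    phi_b <- stats::runif(1, 0, 2 * pi)
    x <- model$breath_amp * sin(2 * pi * model$breath_rate * t + phi_b)
    if (length(beats$times)) {
      delays <- stats::runif(length(beats$times), model$rj_delay_range[1],
                             model$rj_delay_range[2])
      half <- as.integer(ceiling(KERNEL_SUPPORT * fs)) + 1L
      for (k in seq_along(beats$times)) {
        onset <- beats$times[k] + delays[k]
        i0 <- max(1L, as.integer(floor(onset * fs)) + 1L)
        i1 <- min(n, i0 + half)
        if (i0 > n) next
        idx <- i0:i1
        x[idx] <- x[idx] + (model$beat_amp / peak) * kern(t[idx] - onset)
      }
    }
    time_series(x, fs, 0)
  })
}

#' Synthesize quadrature baseband channels from a displacement trace
#'
#' Direct evaluation of the baseband quadrature model (see the package
#' description): target displacement phase-modulates the reflected carrier by
#' `4 pi x / lambda`, observed through imbalanced, offset, noisy I/Q channels.
#'
#' @param x displacement [time_series()] in metres.
#' @param params a [radar_params()].
#' @param seed integer seed for the noise processes.
#' @return list with `radar_ts` elements `i` and `q` at `x$rate`.
#' @export
synthesize_iq <- function(x, params, seed = 1) {
  stopifnot(inherits(x, "radar_ts"), inherits(params, "radar_params"))
  n <- length(x$values)
  with_seed(seed, {
    dtheta <- if (params$phase_noise_sd > 0)
      cumsum(stats::rnorm(n, 0, params$phase_noise_sd)) else numeric(n)
    phase <- params$theta0 + 4 * pi * x$values / params$wavelength + dtheta
    i <- params$A_I * cos(phase) + params$DC_I
    q <- params$A_Q * sin(phase + params$dphi) + params$DC_Q
    if (params$noise_sd > 0) {
      i <- i + stats::rnorm(n, 0, params$noise_sd)
      q <- q + stats::rnorm(n, 0, params$noise_sd)
    }
    list(i = time_series(i, x$rate, x$t0), q = time_series(q, x$rate, x$t0))
  })
}

#' Synthesize a single-lead reference ECG for a beat train
#'
#' Stereotyped P-QRS-T template (Gaussian deflections) centred so each R apex
#' falls exactly on the beat time; the R amplitude is at least five times the
#' P and T amplitudes, plus white baseline noise.
#'
#' @param beats a [beat_train()] of R times.
#' @param fs sampling rate, Hz (250 Hz typical; >= 250 recommended).
#' @param duration duration, s.
#' @param seed integer seed (baseline noise).
#' @param noise_sd baseline noise scale, mV.
#' @return a [time_series()] in mV.
#' @export
synthesize_ecg <- function(beats, fs, duration, seed = 1, noise_sd = 0.02) {
  stopifnot(inherits(beats, "beat_train"), fs > 0, duration > 0)
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  # (amplitude mV, centre offset from R, width sigma)
  waves <- list(P = c(0.15, -0.16, 0.020), Q = c(-0.10, -0.026, 0.008),
                R = c(1.00, 0.00, 0.008), S = c(-0.15, 0.026, 0.008),
                T = c(0.20, 0.22, 0.035))
  with_seed(seed, {
    v <- stats::rnorm(n, 0, noise_sd)
    for (tk in beats$times) {
      # R apex on the nearest sample so the global maximum lands exactly there
      tk_s <- round(tk * fs) / fs
      i0 <- max(1L, as.integer(floor((tk_s - 0.35) * fs)) + 1L)
      i1 <- min(n, as.integer(ceiling((tk_s + 0.45) * fs)) + 1L)
      if (i0 > n || i1 < 1L) next
      tau <- t[i0:i1] - tk_s
      tmpl <- 0
      for (w in waves) tmpl <- tmpl + w[1] * exp(-(tau - w[2])^2 / (2 * w[3]^2))
      v[i0:i1] <- v[i0:i1] + tmpl
    }
    time_series(v, fs, 0)
  })
}

#' Generate a synthetic subject cohort
#'
#' Emulates a study cohort of seated, normally breathing subjects: per-subject
#' multiplicative jitter (+/-15%) on heart rate, breathing parameters, beat
#' amplitude and channel amplitudes; additive jitter on DC offsets and phase
#' imbalance; and a uniformly drawn operating-point phase `theta0` per subject.
#' Each recording carries aligned ECG (250 Hz), I and Q (at `base_params$fs`)
#' channels plus the ground-truth beat train.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param duration recording duration per subject, s.
#' @param base_model a [vital_model()] of cohort-mean vitals.
#' @param base_params a [radar_params()] of nominal radar settings.
#' @param seed master cohort seed.
#' @param ecg_fs ECG sampling rate, Hz.
#' @return list of [subject_recording()] objects.
#' @export
generate_cohort <- function(n_subjects, duration, base_model = vital_model(),
                            base_params = radar_params(), seed = 1,
                            ecg_fs = 250) {
  stopifnot(n_subjects >= 1, duration > 0)
  lapply(seq_len(n_subjects), function(k) {
    sid <- sprintf("S%02d", k)
    sseed <- derive_seed(seed, paste0("subject", k))
    jit <- with_seed(derive_seed(sseed, "jitter"), {
      list(mult = stats::runif(6, 0.85, 1.15),
           dc = stats::runif(2, -0.05, 0.05),
           dphi = stats::runif(1, -0.05, 0.05),
           theta0 = stats::runif(1, 0, 2 * pi))
    })
    model <- base_model
    model$mean_hr <- min(120, max(40, base_model$mean_hr * jit$mult[1]))
    model$hrv_sd <- base_model$hrv_sd * jit$mult[2]
    model$breath_rate <- base_model$breath_rate * jit$mult[3]
    model$breath_amp <- base_model$breath_amp * jit$mult[4]
    model$beat_amp <- base_model$beat_amp * jit$mult[5]
    params <- base_params
    params$A_I <- base_params$A_I * jit$mult[6]
    params$A_Q <- base_params$A_Q * (2 - jit$mult[6]) # opposite-sense imbalance
    params$DC_I <- base_params$DC_I + jit$dc[1]
    params$DC_Q <- base_params$DC_Q + jit$dc[2]
    params$dphi <- base_params$dphi + jit$dphi
    params$theta0 <- jit$theta0
    beats <- generate_beat_train(model, duration, derive_seed(sseed, "beats"))
    x <- chest_displacement(beats, model, params$fs, duration,
                            derive_seed(sseed, "disp"))
    iq <- synthesize_iq(x, params, derive_seed(sseed, "iq"))
    ecg <- synthesize_ecg(beats, ecg_fs, duration, derive_seed(sseed, "ecg"))
    subject_recording(sid, ecg, iq$i, iq$q, truth_beats = beats)
  })
}

#' Write / read a cohort as one recording + beat file pair per subject
#'
#' @param cohort list of [subject_recording()].
#' @param dir destination directory (created if needed).
#' @param config optional resolved configuration list written alongside as
#'   `cohort_config.yaml`.
#' @export
save_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort) {
    write_recording(rec, file.path(dir, paste0(rec$subject_id, ".csv")))
    if (!is.null(rec$truth_beats))
      write_beats(rec$truth_beats,
                  file.path(dir, paste0(rec$subject_id, ".beats.txt")))
  }
  if (!is.null(config))
    yaml::write_yaml(config, file.path(dir, "cohort_config.yaml"))
  invisible(dir)
}

#' @rdname save_cohort
#' @return `load_cohort` returns the list of recordings, truth beats attached
#'   when a matching `.beats.txt` file exists.
#' @export
load_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  lapply(files, function(f) {
    rec <- read_recording(f)
    bf <- sub("\\.csv$", ".beats.txt", f)
    if (file.exists(bf)) rec$truth_beats <- read_beats(bf)
    rec
  })
}
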